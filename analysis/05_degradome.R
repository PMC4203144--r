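#!/usr/bin/env Rscript
# Map the simulated degradome tags, build t-plots with the
# transcript-mean baseline, and categorize cleavage support at each
# ranked target site.

suppressPackageStartupMessages(library(mirheat))
sim_dir <- "results/simulated"
for (f in c("transcripts.fasta", "tags.tsv")) {
  if (!file.exists(file.path(sim_dir, f))) {
    stop("run analysis/02_simulate.R (and 03) first")
  }
}
if (!file.exists("results/ranked_sites.tsv")) {
  stop("run analysis/03_scan_and_rank.R first")
}

fa <- read_fasta(file.path(sim_dir, "transcripts.fasta"))
transcripts <- stats::setNames(fa$residues, fa$id)
tags <- read_tags(file.path(sim_dir, "tags.tsv"),
                  len_range = c(1L, 27L))  # truncated 3'-end tags kept
ranked <- read_tsv_checked("results/ranked_sites.tsv",
                           c("mirna_id", "target_id", "start", "end"))

mp <- suppressWarnings(map_tags(tags, transcripts))
message("Mapped ", sum(mp$assigned), " reads (",
        mp$unmapped, " unmapped, ", length(mp$multi_tags),
        " multi-mapping tags)")

calls <- list()
for (i in seq_len(nrow(ranked))) {
  tp <- build_tplot(mp$counts[[ranked$target_id[i]]],
                    ranked$target_id[i])
  write_tplot_tsv(tp, file.path("results",
                                paste0("tplot_", tp$transcript_id,
                                       ".tsv")))
  calls[[i]] <- call_cleavage(tp, ranked[i, ])
}
calls <- do.call(rbind, calls)
write_tsv(calls, "results/cleavage_calls.tsv")
write_calls_bed(calls, "results/cleavage_calls.bed")
message("Cleavage calls (category 0 = unique maximum above the mean):")
for (i in seq_len(nrow(calls))) {
  message("  ", calls$transcript_id[i], " pos ", calls$position[i],
          ": ", calls$reads[i], " reads, ",
          round(calls$fold_over_mean[i], 1), "x the transcript mean, ",
          "category ", calls$category[i])
}
message("Wrote results/cleavage_calls.{tsv,bed} and per-transcript ",
        "t-plot TSVs")
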