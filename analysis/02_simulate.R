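#!/usr/bin/env Rscript
# Generate the synthetic study inputs used by the downstream analysis
# scripts: a transcriptome with planted miR160a target sites of graded
# mismatch composition, a degradome tag library with signal at each
# canonical cleavage position over Poisson background, a MIR gene with
# an intron-hosted designed hairpin, and replicated Ct tables with a
# known 13-fold heat induction.

suppressPackageStartupMessages(library(mirheat))
SEED <- 160L  # fixed workflow seed
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

mirna <- suppressWarnings(barley_mir_models())$MIR160a$mirna_seq
message("Guide miRNA: miR160a, ", nchar(mirna), " nt")

specs <- list(site_spec(0, 0),                      # perfect site
              site_spec(1, 1, mm_positions = 15L),  # 1 MM + 1 G:U
              site_spec(2, 1, mm_positions = c(14L, 18L)),
              NULL)                                 # decoy
sim <- make_target_transcriptome(
  mirna, n_transcripts = 4L, transcript_length = 1000L,
  site_specs = specs, seed = SEED,
  site_positions = c(301L, 487L, 652L, NA))
write_fasta(sim$transcripts, file.path(out, "transcripts.fasta"))
write_tsv(sim$truth, file.path(out, "truth.tsv"))
message("Simulated ", length(sim$transcripts), " transcripts; ",
        sum(sim$truth$has_site), " planted sites with total scores ",
        paste(na.omit(sim$truth$total_score), collapse = ", "))

tags <- make_degradome_library(sim$truth, sim$transcripts,
                               signal_reads = 50L, background_rate = 1.0,
                               seed = SEED + 1L)
write_tsv(tags, file.path(out, "tags.tsv"))
message("Degradome library: ", nrow(tags), " distinct tags, ",
        sum(tags$count), " reads (signal 50/site over Poisson(1) noise)")

gene <- make_mir_gene(exon_lengths = c(206, 47, 99, 348),
                      intron_lengths = c(73, 211, 214),
                      host_kind = "intron", host_index = 2L,
                      stem_len = 21L, seed = SEED + 2L)
write_fasta(stats::setNames(gene$precursor, gene$model$gene_id),
            file.path(out, "precursor.fasta"))
write_models_tsv(list(gene$model), file.path(out, "synth_gene.tsv"))
message("Synthetic MIR gene mirrors the 4-exon/3-intron topology with ",
        "the hairpin in intron 2 (gene ", gene$model$gene_length, " bp)")

ct <- make_ct_table(gene_id = "pri-miR-synth", true_fold = 13,
                    noise_sd_ct = 0.1, n_reps = 3L,
                    timepoints = c(3, 6, 24), seed = SEED + 3L)
write_tsv(ct, file.path(out, "ct_table.tsv"))
message("Ct table: 3 replicates x 2 conditions x 3 timepoints, ",
        "true fold 13, Ct noise SD 0.1")
message("Wrote ", out, "/{transcripts.fasta, truth.tsv, tags.tsv, ",
        "precursor.fasta, synth_gene.tsv, ct_table.tsv}")
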