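# End-to-end orchestration over synthetic data: simulate -> scan ->
# attach energies -> filter/rank -> fold the synthetic precursor ->
# degradome mapping and cleavage calls -> Ct quantification -> report.
# Filters run in a fixed order (mismatch discard rules at scan time, then
# the MFE selection, then MFE ranking); the per-stage attrition is logged
# in the manifest because, while the surviving set is order-invariant,
# the logged counts are not.

#' Default pipeline configuration
#'
#' @param seed master seed; every stage derives its stream from it.
#' @param mirna miRNA sequence; `NULL` draws a random 21-mer.
#' @param n_transcripts,transcript_length synthetic transcriptome shape.
#' @param site_specs per-transcript [site_spec()] list (`NULL` entries =
#'   decoys); default plants a perfect site in every transcript but one.
#' @param signal_reads,background_rate degradome library parameters.
#' @param true_fold,noise_sd_ct,n_reps Ct table parameters.
#' @param scan a [scan_config()].
#' @param flank hairpin folding flank (nt).
#' @return nested configuration list.
#' @export
pipeline_config <- function(seed = 1L, mirna = NULL, n_transcripts = 4L,
                            transcript_length = 1000L, site_specs = NULL,
                            signal_reads = 50L, background_rate = 1.0,
                            true_fold = 13, noise_sd_ct = 0.1,
                            n_reps = 3L, scan = scan_config(),
                            flank = 120L) {
  if (is.null(site_specs)) {
    site_specs <- c(rep(list(site_spec()), max(0L, n_transcripts - 1L)),
                    list(NULL))[seq_len(n_transcripts)]
  }
  list(seed = as.integer(seed), mirna = mirna,
       n_transcripts = n_transcripts,
       transcript_length = transcript_length, site_specs = site_specs,
       signal_reads = signal_reads, background_rate = background_rate,
       true_fold = true_fold, noise_sd_ct = noise_sd_ct, n_reps = n_reps,
       scan = scan, flank = flank)
}

#' Run the full synthetic pipeline
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created); stage outputs are written
#'   with stable names and a `manifest.json` records the config snapshot,
#'   seed, per-stage record counts and output checksums.
#' @return invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  mirna <- config$mirna
  if (is.null(mirna)) {
    mirna <- with_seed(seed * 13L + 1L, random_rna(21L))
  }

  sim <- stage("simulate", make_target_transcriptome(
    mirna, config$n_transcripts, config$transcript_length,
    config$site_specs, seed = seed, config = config$scan))
  counts$transcripts <- length(sim$transcripts)
  counts$planted_sites <- sum(sim$truth$has_site)
  if (length(sim$transcripts)) {
    write_fasta(sim$transcripts, file.path(out_dir, "transcripts.fasta"))
  } else {
    file.create(file.path(out_dir, "transcripts.fasta"))
  }
  write_tsv(sim$truth, file.path(out_dir, "truth.tsv"))

  aln <- stage("scan", if (length(sim$transcripts)) {
    scan_many(stats::setNames(list(mirna), "synth_mir"),
              as.list(sim$transcripts), config$scan)
  } else {
    scan_many(c(synth_mir = mirna), list(), config$scan)
  })
  counts$windows_scanned <- attr(aln, "windows_scanned")
  counts$scan_survivors <- nrow(aln)

  model <- load_energy_model()
  aln <- stage("energy", attach_energies(
    aln, c(synth_mir = mirna), sim$transcripts, model))
  ranked <- stage("rank", filter_and_rank(aln, config$scan))
  counts$mfe_survivors <- nrow(ranked)
  write_alignments_tsv(ranked, file.path(out_dir, "ranked_sites.tsv"))
  if (nrow(ranked)) {
    write_alignments_gff3(ranked, file.path(out_dir, "ranked_sites.gff3"))
  }

  gene <- stage("gene", make_mir_gene(
    exon_lengths = c(220, 100, 350), intron_lengths = c(80, 260),
    host_kind = "intron", host_index = 2L, stem_len = nchar(mirna),
    seed = seed * 13L + 2L))
  hp <- stage("fold", fold_precursor(
    gene$precursor, gene$model$mirna_span, gene$model$star_span,
    flank = config$flank, model = model))
  counts$hairpin_pairs <- nrow(hp$pairs)
  write_vienna(hp, file.path(out_dir, "hairpin.vienna"),
               id = gene$model$gene_id)
  write_tsv(data.frame(gene_id = gene$model$gene_id, mfe = hp$mfe,
                       duplex_paired_fraction = hp$duplex_paired_fraction),
            file.path(out_dir, "hairpin_summary.tsv"))

  tags <- stage("degradome", make_degradome_library(
    sim$truth, sim$transcripts, config$signal_reads,
    config$background_rate, seed = seed * 13L + 3L))
  counts$tags <- nrow(tags)
  write_tsv(tags, file.path(out_dir, "tags.tsv"))
  calls <- NULL
  if (nrow(tags) && length(sim$transcripts)) {
    mp <- stage("map", map_tags(tags, sim$transcripts))
    call_rows <- list()
    for (i in seq_len(nrow(ranked))) {
      tp <- build_tplot(mp$counts[[ranked$target_id[i]]],
                        ranked$target_id[i])
      call_rows[[i]] <- call_cleavage(tp, ranked[i, ])
    }
    calls <- do.call(rbind, call_rows)
    if (!is.null(calls)) {
      write_tsv(calls, file.path(out_dir, "cleavage_calls.tsv"))
      write_calls_bed(calls, file.path(out_dir, "cleavage_calls.bed"))
    }
  }
  counts$cleavage_calls <- if (is.null(calls)) 0L else nrow(calls)

  ct <- stage("ct", make_ct_table(
    true_fold = config$true_fold, noise_sd_ct = config$noise_sd_ct,
    n_reps = config$n_reps, seed = seed * 13L + 4L))
  write_tsv(ct, file.path(out_dir, "ct_table.tsv"))
  fc <- stage("quantify", summarize_fold_changes(ct))
  write_tsv(fc, file.path(out_dir, "fold_changes.tsv"))
  counts$fold_change_rows <- nrow(fc)

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    tool = "mirheat",
    version = as.character(utils::packageVersion("mirheat")),
    seed = seed,
    mirna = mirna,
    config = config[setdiff(names(config), c("site_specs", "scan"))],
    scan = unclass(config$scan),
    n_site_specs = length(config$site_specs),
    counts = counts,
    outputs = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$outputs) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(mirna = mirna, sim = sim, alignments = aln,
                 ranked = ranked, gene = gene, hairpin = hp, tags = tags,
                 calls = calls, ct = ct, fold_changes = fc,
                 manifest = manifest))
}
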