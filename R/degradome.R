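# Degradome (PARE) analysis: 26-27-nt tags are 5'-end signatures of
# cleaved transcripts. Tags map by exact prefix match; per-position
# 5'-end counts form the t-plot, whose transcript-wide mean is the
# baseline for categorizing cleavage-site support at the canonical
# slicing position (between target nucleotides paired to miRNA
# positions 10 and 11).

#' Read a degradome tag library
#'
#' TSV with columns `tag_seq` and `count`, or FASTA with `count=N` in the
#' header. Sequences are normalized to RNA; tag lengths outside
#' `len_range` are rejected.
#'
#' @param path file path (`.tsv`/`.txt` or FASTA otherwise).
#' @param len_range allowed tag lengths, default `c(26, 27)`.
#' @return data.frame with `tag_seq`, `count`.
#' @export
read_tags <- function(path, len_range = c(26L, 27L)) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
    df <- read_tsv_checked(path, c("tag_seq", "count"))
    df$tag_seq <- normalize_rna(df$tag_seq)
  } else {
    fa <- read_fasta(path)
    cnt <- suppressWarnings(as.integer(sub(".*count=(\\d+).*", "\\1",
                                           paste(fa$id, fa$description))))
    if (anyNA(cnt)) stop("read_tags: FASTA headers must carry count=N")
    df <- data.frame(tag_seq = fa$residues, count = cnt,
                     stringsAsFactors = FALSE)
  }
  if (any(df$count < 1L)) stop("read_tags: counts must be >= 1")
  n <- nchar(df$tag_seq)
  if (any(n < len_range[1] | n > len_range[2])) {
    stop("read_tags: tag length(s) outside ", len_range[1], "-",
         len_range[2], " nt")
  }
  df
}

#' Map degradome tags onto transcripts
#'
#' The 5'-most `match_len` nucleotides of each tag are matched exactly
#' (sense strand) against every transcript; each hit adds the tag's count
#' to the t-plot at the match start position. Tags matching several loci
#' increment every locus ("count-to-all") and are flagged; under the
#' `"fractional"` policy the count is split evenly across loci instead.
#'
#' @param tags data.frame with `tag_seq`, `count` (see [read_tags()]).
#' @param transcripts named character vector of transcript sequences.
#' @param match_len prefix length used for matching (default 20; tags
#'   shorter than this are skipped with a warning).
#' @param multimap `"all"` (default) or `"fractional"`.
#' @return list with `counts` (named list of per-position numeric vectors,
#'   one per transcript), `assigned` (reads assigned per transcript),
#'   `unmapped` (total count of tags matching nowhere), `multi_tags`
#'   (indices of multi-mapping tags).
#' @export
map_tags <- function(tags, transcripts, match_len = 20L,
                     multimap = c("all", "fractional")) {
  multimap <- match.arg(multimap)
  short <- nchar(tags$tag_seq) < match_len
  if (any(short)) {
    warning(sum(short), " tag(s) shorter than match_len skipped")
    tags <- tags[!short, , drop = FALSE]
  }
  counts <- lapply(transcripts, function(s) numeric(nchar(s)))
  if (nrow(tags) == 0L || length(transcripts) == 0L) {
    return(list(counts = counts,
                assigned = vapply(counts, sum, numeric(1)),
                unmapped = if (nrow(tags)) sum(tags$count) else 0,
                multi_tags = integer(0)))
  }
  # constant-width prefix dictionary: one pass per transcript
  prefs <- Biostrings::DNAStringSet(
    chartr("U", "T", substr(tags$tag_seq, 1L, match_len)))
  pd <- Biostrings::PDict(prefs)
  starts_by_tx <- lapply(transcripts, function(s) {
    m <- Biostrings::matchPDict(pd, Biostrings::DNAString(chartr("U", "T",
                                                                 s)))
    Biostrings::startIndex(m)
  })
  nhit <- Reduce(`+`, lapply(starts_by_tx, function(x)
    lengths(x, use.names = FALSE)))
  unmapped <- sum(tags$count[nhit == 0L])
  multi <- which(nhit > 1L)
  inc <- if (multimap == "fractional") {
    ifelse(nhit > 0L, tags$count / pmax(nhit, 1L), 0)
  } else tags$count
  for (ti in names(transcripts)) {
    st <- starts_by_tx[[ti]]
    pos <- unlist(st, use.names = FALSE)
    if (length(pos) == 0L) next
    wt <- rep(inc, lengths(st, use.names = FALSE))
    add <- rowsum(wt, pos)
    counts[[ti]][as.integer(rownames(add))] <-
      counts[[ti]][as.integer(rownames(add))] + add[, 1]
  }
  list(counts = counts,
       assigned = vapply(counts, sum, numeric(1)),
       unmapped = unmapped,
       multi_tags = multi)
}

#' Build a t-plot from per-position counts
#'
#' @param counts numeric vector of 5'-end read counts along a transcript.
#' @param transcript_id identifier.
#' @return object of class `tplot`: list with `transcript_id`, `counts`,
#'   `mean_count` (total reads / transcript length).
#' @export
build_tplot <- function(counts, transcript_id = "transcript") {
  if (length(counts) < 1L) stop("build_tplot: zero-length transcript")
  if (any(counts < 0)) stop("build_tplot: negative counts")
  structure(list(transcript_id = transcript_id, counts = counts,
                 mean_count = sum(counts) / length(counts)),
            class = "tplot")
}

#' @export
print.tplot <- function(x, ...) {
  cat("<tplot> ", x$transcript_id, ": ", length(x$counts),
      " nt, ", sum(x$counts), " reads, mean ",
      sprintf("%.3f", x$mean_count), "/position\n", sep = "")
  invisible(x)
}

#' Expected cleavage position for a duplex alignment
#'
#' Slicing occurs between the target nucleotides paired to miRNA
#' positions 10 and 11; the reported coordinate is the 5' end of the
#' downstream cleavage fragment, i.e. the target position paired to
#' miRNA position 10. With antiparallel pairing over `(start, end)` this
#' is `end - 9`.
#'
#' @param alignment one row of a `duplex_alignments` table (or any list
#'   with `start`/`end`).
#' @return 1-based transcript coordinate.
#' @export
expected_cleavage_position <- function(alignment) {
  len <- alignment$end - alignment$start + 1L
  if (any(len < 11L)) {
    stop("expected_cleavage_position: alignment shorter than 11 nt")
  }
  as.integer(alignment$end - 9L)
}

#' Categorize degradome support for a predicted cleavage site
#'
#' Reads at the site = maximum t-plot count within `tolerance` of the
#' expected position. Categories (smaller = stronger evidence):
#' 0 = unique transcript-wide maximum and above the mean; 1 = tied
#' maximum and above the mean; 2 = above the mean but not a maximum;
#' 3 = more than 1 read but at or below the mean; 4 = otherwise.
#'
#' @param tplot a [build_tplot()] object.
#' @param alignment one `duplex_alignments` row on the same transcript.
#' @param tolerance positional slack in nt (default 1).
#' @return data.frame of class `cleavage_call`: `transcript_id`,
#'   `mirna_id`, `position` (expected site), `reads`, `mean_count`,
#'   `fold_over_mean`, `category`.
#' @export
call_cleavage <- function(tplot, alignment, tolerance = 1L) {
  counts <- tplot$counts
  L <- length(counts)
  pos <- expected_cleavage_position(alignment)
  if (pos < 1L || pos > L) stop("call_cleavage: expected position ", pos,
                                " outside transcript")
  win <- max(1L, pos - tolerance):min(L, pos + tolerance)
  reads <- max(counts[win])
  mx <- max(counts)
  n_at_max <- sum(counts == mx)
  above <- reads > tplot$mean_count
  category <- if (reads > 0 && reads == mx && n_at_max == 1L && above) 0L
  else if (reads > 0 && reads == mx && above) 1L
  else if (above) 2L
  else if (reads > 1) 3L
  else 4L
  structure(data.frame(
    transcript_id = tplot$transcript_id,
    mirna_id = if (!is.null(alignment$mirna_id)) alignment$mirna_id else NA,
    position = pos,
    reads = reads,
    mean_count = tplot$mean_count,
    fold_over_mean = if (tplot$mean_count > 0) reads / tplot$mean_count
    else NA_real_,
    category = category,
    stringsAsFactors = FALSE
  ), class = c("cleavage_call", "data.frame"))
}

#' Write t-plot(s) as TSV (position, count)
#' @param tplot a `tplot`. @param path output path.
#' @export
write_tplot_tsv <- function(tplot, path) {
  write_tsv(data.frame(transcript_id = tplot$transcript_id,
                       position = seq_along(tplot$counts),
                       count = tplot$counts), path)
}

#' Export cleavage calls as BED6
#'
#' 0-based half-open intervals (BED dialect); score = supporting reads.
#'
#' @param calls row-bound `cleavage_call` data.frame.
#' @param path output path.
#' @export
write_calls_bed <- function(calls, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = calls$transcript_id,
    ranges = IRanges::IRanges(calls$position, width = 1L),
    strand = "+")
  S4Vectors::mcols(gr)$name <- paste0(calls$mirna_id, "_site")
  S4Vectors::mcols(gr)$score <- calls$reads
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' t-plot figure
#'
#' Per-position degradome 5'-end counts with the transcript-mean baseline
#' as a dashed line and the called site highlighted.
#'
#' @param tplot a `tplot`. @param call optional `cleavage_call` row.
#' @return a ggplot object.
#' @export
plot_tplot <- function(tplot, call = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_tplot needs ggplot2")
  }
  df <- data.frame(position = seq_along(tplot$counts),
                   count = tplot$counts)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                        y = .data$count)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0)) +
    ggplot2::geom_hline(yintercept = tplot$mean_count,
                        linetype = "dashed") +
    ggplot2::labs(x = "transcript position",
                  y = "degradome 5'-end reads",
                  title = tplot$transcript_id)
  if (!is.null(call)) {
    p <- p + ggplot2::annotate("point", x = call$position, y = call$reads,
                               shape = 25, fill = "red")
  }
  p
}
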