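# Ungapped miRNA:target scanning under the mismatch-point scheme:
# G:U wobble = 0.5 point, any other substitution = 1 point, no indels.
# A window is discarded when its total score reaches 4 points or its
# substitution score over sRNA positions 1-12 exceeds 2.5 points.

# per-base score and class lookup tables, rows = miRNA base, cols = target
.pair_score_mat <- local({
  m <- matrix(1, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  m["A", "U"] <- m["U", "A"] <- m["G", "C"] <- m["C", "G"] <- 0
  m["G", "U"] <- m["U", "G"] <- 0.5
  m
})
.pair_class_mat <- local({
  m <- matrix("MM", 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  m["A", "U"] <- m["U", "A"] <- m["G", "C"] <- m["C", "G"] <- "WC"
  m["G", "U"] <- m["U", "G"] <- "GU"
  m
})

#' Scanner configuration
#'
#' Thresholds of the discard/filter scheme: duplexes with total mismatch
#' score >= `max_total_score` are discarded (the bound is exclusive for
#' retention), duplexes with seed score (sRNA positions 1-12) strictly
#' above `max_seed12_score` are discarded, and only duplexes with
#' hybridization MFE <= `mfe_threshold` kcal/mol survive the energy filter.
#'
#' @param max_total_score discard at or above this total score (default 4).
#' @param max_seed12_score discard strictly above this seed score
#'   (default 2.5).
#' @param mfe_threshold inclusive MFE cutoff, kcal/mol (default -15).
#' @param discard_combination `"either"` (default): either score rule alone
#'   discards; `"both"`: only the conjunction of the two discards (the
#'   literal reading of the combined rule).
#' @return a `scan_config` list.
#' @export
scan_config <- function(max_total_score = 4, max_seed12_score = 2.5,
                        mfe_threshold = -15,
                        discard_combination = c("either", "both")) {
  structure(list(
    max_total_score = max_total_score,
    max_seed12_score = max_seed12_score,
    mfe_threshold = mfe_threshold,
    discard_combination = match.arg(discard_combination)
  ), class = "scan_config")
}

#' Classify one miRNA:target base pairing
#'
#' @param mirna_base,target_base single bases in \{A,C,G,U\} (vectorized).
#' @return `"WC"`, `"GU"` or `"MM"` per element.
#' @export
classify_pair <- function(mirna_base, target_base) {
  ok <- mirna_base %in% RNA_BASES & target_base %in% RNA_BASES
  if (!all(ok)) stop("classify_pair: invalid base (caller must exclude N)")
  .pair_class_mat[cbind(mirna_base, target_base)]
}

#' Score one miRNA against one equal-length target window
#'
#' The duplex is ungapped and antiparallel: miRNA position i (1 = 5' end)
#' pairs the target-window position `length - i + 1`. Both sequences are
#' given 5' to 3' (the window on the sense strand of the mRNA).
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param target_window target window, 5'->3', same length.
#' @return list with `pair_classes` (character vector along miRNA
#'   positions), `pairs` (compact string, one of W/G/M per position),
#'   `total_score` and `seed12_score`.
#' @export
score_site <- function(mirna, target_window) {
  if (nchar(mirna) != nchar(target_window)) {
    stop("score_site: miRNA and window lengths differ (no indels allowed)")
  }
  m <- strsplit(mirna, "", fixed = TRUE)[[1]]
  t5 <- strsplit(target_window, "", fixed = TRUE)[[1]]
  tw <- rev(t5)  # base paired with miRNA position i
  cls <- classify_pair(m, tw)
  sc <- .pair_score_mat[cbind(m, tw)]
  seed <- seq_len(min(12L, length(m)))
  list(pair_classes = cls,
       pairs = paste(substr(cls, 1L, 1L), collapse = ""),
       total_score = sum(sc),
       seed12_score = sum(sc[seed]))
}

.discard <- function(total, seed, config) {
  over_total <- total >= config$max_total_score
  over_seed <- seed > config$max_seed12_score
  if (config$discard_combination == "either") over_total | over_seed
  else over_total & over_seed
}

#' Scan a transcript exhaustively for miRNA target sites
#'
#' Every window of width `nchar(mirna)` on the sense strand is scored under
#' the mismatch-point scheme; windows surviving the discard rules are
#' returned. Windows containing N are skipped and counted. Exhaustive and
#' deterministic; site discovery by scoring alone, with the MFE filter
#' applied separately after [attach_energies()].
#'
#' @param mirna miRNA sequence (5'->3', ACGU).
#' @param transcript transcript sequence (sense strand, ACGUN).
#' @param config a [scan_config()].
#' @param mirna_id,target_id identifiers carried into the result.
#' @return data.frame of class `duplex_alignments`: one row per surviving
#'   window with `mirna_id`, `target_id`, `start`, `end` (1-based
#'   inclusive), `pairs`, `total_score`, `seed12_score`, `mfe` (NA until
#'   energies attached), `rank` (NA until ranked). Attributes
#'   `windows_scanned` and `windows_skipped_n` record scan effort.
#' @export
scan_transcript <- function(mirna, transcript, config = scan_config(),
                            mirna_id = "mirna", target_id = "target") {
  L <- nchar(mirna)
  empty <- data.frame(mirna_id = character(), target_id = character(),
                      start = integer(), end = integer(),
                      pairs = character(), total_score = numeric(),
                      seed12_score = numeric(), mfe = numeric(),
                      rank = integer(), stringsAsFactors = FALSE)
  class(empty) <- c("duplex_alignments", "data.frame")
  if (nchar(transcript) < L) {
    warning("transcript '", target_id, "' shorter than miRNA; empty scan")
    attr(empty, "windows_scanned") <- 0L
    attr(empty, "windows_skipped_n") <- 0L
    return(empty)
  }
  menc <- match(strsplit(mirna, "", fixed = TRUE)[[1]], RNA_BASES)
  if (anyNA(menc)) stop("scan_transcript: miRNA must be ACGU")
  tenc <- match(strsplit(transcript, "", fixed = TRUE)[[1]], RNA_BASES)
  nwin <- nchar(transcript) - L + 1L
  win <- seq_len(nwin)
  # miRNA position i pairs transcript position (start + L - i)
  score <- matrix(0, nrow = L, ncol = nwin)
  cls <- matrix("", nrow = L, ncol = nwin)
  for (i in seq_len(L)) {
    tb <- tenc[win + L - i]
    score[i, ] <- ifelse(is.na(tb), NA, .pair_score_mat[cbind(menc[i], tb)])
    cls[i, ] <- ifelse(is.na(tb), "N",
                       substr(.pair_class_mat[cbind(menc[i], tb)], 1L, 1L))
  }
  totals <- colSums(score)
  skipped <- is.na(totals)
  seed <- seq_len(min(12L, L))
  seeds <- colSums(score[seed, , drop = FALSE])
  keep <- !skipped & !.discard(totals, seeds, config)
  res <- data.frame(
    mirna_id = rep(mirna_id, sum(keep)),
    target_id = rep(target_id, sum(keep)),
    start = win[keep],
    end = win[keep] + L - 1L,
    pairs = vapply(which(keep), function(s)
      paste(cls[, s], collapse = ""), character(1)),
    total_score = totals[keep],
    seed12_score = seeds[keep],
    mfe = rep(NA_real_, sum(keep)),
    rank = rep(NA_integer_, sum(keep)),
    stringsAsFactors = FALSE
  )
  if (sum(skipped) > 0L) {
    message("scan: ", sum(skipped), " window(s) containing N skipped on '",
            target_id, "'")
  }
  class(res) <- c("duplex_alignments", "data.frame")
  attr(res, "windows_scanned") <- nwin
  attr(res, "windows_skipped_n") <- sum(skipped)
  res
}

#' Scan many miRNAs against many transcripts
#'
#' @param mirnas,transcripts named character vectors (names = ids).
#' @param config a [scan_config()].
#' @return row-bound `duplex_alignments` with summed scan attributes.
#' @export
scan_many <- function(mirnas, transcripts, config = scan_config()) {
  res <- list()
  scanned <- skipped <- 0L
  for (mi in names(mirnas)) {
    for (ti in names(transcripts)) {
      r <- scan_transcript(mirnas[[mi]], transcripts[[ti]], config,
                           mirna_id = mi, target_id = ti)
      scanned <- scanned + attr(r, "windows_scanned")
      skipped <- skipped + attr(r, "windows_skipped_n")
      res[[length(res) + 1L]] <- r
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(mirna_id = character(), target_id = character(),
               start = integer(), end = integer(), pairs = character(),
               total_score = numeric(), seed12_score = numeric(),
               mfe = numeric(), rank = integer(), stringsAsFactors = FALSE)
  class(out) <- c("duplex_alignments", "data.frame")
  attr(out, "windows_scanned") <- scanned
  attr(out, "windows_skipped_n") <- skipped
  out
}

#' Filter by MFE and rank duplexes
#'
#' Retains alignments with `mfe <= config$mfe_threshold` (the bound is
#' inclusive: an MFE exactly at the threshold survives) and ranks the
#' survivors by ascending MFE (most stable first); ties break by total
#' score (ascending), then target id, then start coordinate.
#'
#' @param alignments `duplex_alignments` with `mfe` populated.
#' @param config a [scan_config()].
#' @return the retained alignments, ordered, with `rank` = 1..k.
#' @export
filter_and_rank <- function(alignments, config = scan_config()) {
  if (nrow(alignments) > 0L && anyNA(alignments$mfe)) {
    stop("filter_and_rank: mfe not populated; run attach_energies() first")
  }
  keep <- alignments[alignments$mfe <= config$mfe_threshold, , drop = FALSE]
  ord <- order(keep$mfe, keep$total_score, keep$target_id, keep$start)
  keep <- keep[ord, , drop = FALSE]
  keep$rank <- seq_len(nrow(keep))
  rownames(keep) <- NULL
  class(keep) <- c("duplex_alignments", "data.frame")
  keep
}

#' Run-length pair string for reporting ("WC×9,GU,WC×5,...")
#' @param pairs compact W/G/M pair string (one char per miRNA position).
#' @return human-readable run-length encoding.
#' @export
format_pair_string <- function(pairs) {
  vapply(pairs, function(p) {
    r <- rle(strsplit(p, "", fixed = TRUE)[[1]])
    lab <- c(W = "WC", G = "GU", M = "MM", N = "N")[r$values]
    paste(ifelse(r$lengths > 1L,
                 paste0(lab, "×", r$lengths), lab), collapse = ",")
  }, character(1), USE.NAMES = FALSE)
}

#' Write duplex alignments as TSV
#' @param alignments `duplex_alignments`. @param path output path.
#' @export
write_alignments_tsv <- function(alignments, path) {
  out <- alignments
  out$pairs <- format_pair_string(out$pairs)
  write_tsv(out, path)
}

#' Export duplex alignment sites as GFF3
#' @param alignments `duplex_alignments`. @param path output path.
#' @export
write_alignments_gff3 <- function(alignments, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = alignments$target_id,
    ranges = IRanges::IRanges(alignments$start, alignments$end),
    strand = "+",
    type = "miRNA_target_site",
    ID = paste0(alignments$mirna_id, ":", alignments$target_id, ":",
                alignments$start),
    Name = alignments$mirna_id,
    score = alignments$total_score
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
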