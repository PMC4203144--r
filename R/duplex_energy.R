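# Hybridization free energy of an ungapped miRNA:target duplex under the
# nearest-neighbor model: duplex initiation + stacking over adjacent paired
# columns (WC or G:U wobble; wobble pairs stack) + a per-column penalty for
# mismatch columns (1x1 internal-loop approximation) + a terminal penalty
# for each duplex end whose closing pair is A:U or G:U.

#' Nearest-neighbor free energy of an ungapped duplex
#'
#' @param mirna miRNA sequence 5'->3' (ACGU).
#' @param target_window equal-length target window 5'->3' (sense strand).
#' @param pairs optional compact W/G/M pair string (as produced by
#'   [score_site()] / [scan_transcript()]); recomputed when `NULL`, and
#'   checked against the sequences when given.
#' @param model an [load_energy_model()] object.
#' @return dG37 in kcal/mol (more negative = more stable).
#' @export
duplex_mfe <- function(mirna, target_window, pairs = NULL,
                       model = load_energy_model()) {
  L <- nchar(mirna)
  if (nchar(target_window) != L) stop("duplex_mfe: length mismatch")
  m <- strsplit(mirna, "", fixed = TRUE)[[1]]
  tw <- rev(strsplit(target_window, "", fixed = TRUE)[[1]])
  pname <- pair_name(m, tw)  # NA where column cannot pair
  if (is.null(pairs)) {
    cls <- substr(classify_pair(m, tw), 1L, 1L)
  } else {
    cls <- strsplit(pairs, "", fixed = TRUE)[[1]]
    if (length(cls) != L) stop("duplex_mfe: pairs string length mismatch")
    if (any(cls %in% c("W", "G") & is.na(pname))) {
      stop("duplex_mfe: column classified as pairing but bases incompatible")
    }
  }
  paired <- cls %in% c("W", "G")
  dG <- model$duplex_init
  if (any(paired)) {
    idx <- which(paired)
    adj <- idx[which(diff(idx) == 1L)]         # stack between col i, i+1
    if (length(adj)) {
      dG <- dG + sum(model$stack[cbind(pname[adj], pname[adj + 1L])])
    }
    ends <- unique(c(idx[1L], idx[length(idx)]))
    weak <- pname[ends] %in% c("AU", "UA", "GU", "UG")
    dG <- dG + model$terminal_au * sum(weak)
  }
  dG + model$mismatch_penalty * sum(cls == "M")
}

#' Attach duplex free energies to scanned alignments
#'
#' Batch application of [duplex_mfe()] over a `duplex_alignments` table;
#' results are independent of row order.
#'
#' @param alignments `duplex_alignments` from [scan_transcript()].
#' @param mirnas,transcripts named character vectors of sequences.
#' @param model an [load_energy_model()] object.
#' @return `alignments` with the `mfe` column populated.
#' @export
attach_energies <- function(alignments, mirnas, transcripts,
                            model = load_energy_model()) {
  if (nrow(alignments) == 0L) return(alignments)
  miss_m <- setdiff(unique(alignments$mirna_id), names(mirnas))
  miss_t <- setdiff(unique(alignments$target_id), names(transcripts))
  if (length(miss_m) || length(miss_t)) {
    stop("attach_energies: missing sequence(s) for ",
         paste(c(miss_m, miss_t), collapse = ", "))
  }
  alignments$mfe <- vapply(seq_len(nrow(alignments)), function(i) {
    w <- substr(transcripts[[alignments$target_id[i]]],
                alignments$start[i], alignments$end[i])
    duplex_mfe(mirnas[[alignments$mirna_id[i]]], w,
               pairs = alignments$pairs[i], model = model)
  }, numeric(1))
  alignments
}
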