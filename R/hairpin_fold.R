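# Pri-miRNA hairpin folding: a window of ~120 nt on each side of the
# mature miRNA is folded to its minimum-free-energy secondary structure
# (no pseudoknots, minimum hairpin loop 3 nt) and the miRNA/miRNA* duplex
# pairing is read off the MFE structure.

#' Extract the folding window around a miRNA
#'
#' @param precursor precursor (pri-miRNA) sequence.
#' @param mirna_span 1-based inclusive span of the miRNA in the precursor.
#' @param flank nucleotides of context on each side (default 120); clipped
#'   at the precursor ends.
#' @return list with `window_seq`, `window_offset` (1-based precursor
#'   coordinate of window position 1) and `mirna_window_span`.
#' @export
extract_window <- function(precursor, mirna_span, flank = 120L) {
  L <- nchar(precursor)
  mirna_span <- as.integer(mirna_span)
  if (mirna_span[1] < 1L || mirna_span[2] > L ||
      mirna_span[1] > mirna_span[2]) {
    stop("coordinate error: miRNA span outside precursor")
  }
  a <- max(1L, mirna_span[1] - as.integer(flank))
  b <- min(L, mirna_span[2] + as.integer(flank))
  list(window_seq = substr(precursor, a, b),
       window_offset = a,
       mirna_window_span = mirna_span - a + 1L)
}

#' Fold a window to its MFE secondary structure
#'
#' Dynamic-programming MFE folding under the package energy model
#' (stacks, loop-length initiation tables, affine multiloop terms);
#' deterministic traceback prefers 5'-most explanations among co-optimal
#' structures. Under [pair_max_model()] the objective reduces to base-pair
#' maximization (Nussinov).
#'
#' @param window_seq RNA string (ACGU; windows containing N are refused).
#' @param model an [load_energy_model()] object.
#' @param max_len refusal cap on window length (default 1000; folding is
#'   O(n^3)).
#' @return object of class `hairpin_structure`: list with `window_seq`,
#'   `pairs` (data.frame i < j, 1-based window positions), `dot_bracket`,
#'   `mfe` (kcal/mol), plus `window_offset`, `mirna_window_span`,
#'   `star_window_span`, `duplex_paired_fraction` when filled by
#'   [fold_precursor()].
#' @export
fold_mfe <- function(window_seq, model = load_energy_model(),
                     max_len = 1000L) {
  if (grepl("N", window_seq, fixed = TRUE)) {
    stop("fold_mfe: window contains N; excluded from folding")
  }
  enc <- match(strsplit(window_seq, "", fixed = TRUE)[[1]], RNA_BASES)
  if (anyNA(enc)) stop("fold_mfe: window must be ACGU")
  if (length(enc) > max_len) {
    stop("fold_mfe: window of ", length(enc), " nt exceeds cap ", max_len)
  }
  r <- .fold_mfe_cpp(enc, model$stack, model$hairpin, model$bulge,
                     model$internal, model$loop_extrap_slope,
                     model$max_loop, model$ml_close, model$ml_branch,
                     model$ml_unpaired, model$pair_bonus)
  pairs <- data.frame(i = r$i, j = r$j)
  pairs <- pairs[order(pairs$i), , drop = FALSE]
  rownames(pairs) <- NULL
  db <- rep(".", length(enc))
  db[pairs$i] <- "("
  db[pairs$j] <- ")"
  structure(list(window_seq = window_seq, window_offset = 1L,
                 pairs = pairs, dot_bracket = paste(db, collapse = ""),
                 mfe = r$mfe, mirna_window_span = NULL,
                 star_window_span = NULL,
                 duplex_paired_fraction = NA_real_),
            class = "hairpin_structure")
}

#' @export
print.hairpin_structure <- function(x, ...) {
  cat("<hairpin_structure> ", nchar(x$window_seq), " nt, ",
      nrow(x$pairs), " pairs, MFE ", sprintf("%.2f", x$mfe),
      " kcal/mol\n", sep = "")
  if (!is.na(x$duplex_paired_fraction)) {
    cat("  miRNA/miRNA* duplex paired fraction: ",
        sprintf("%.3f", x$duplex_paired_fraction), "\n", sep = "")
  }
  invisible(x)
}

#' miRNA/miRNA* pairing in a folded structure
#'
#' Fraction of miRNA positions paired, in the MFE structure, to a position
#' inside the star span. The two spans must be disjoint.
#'
#' @param structure a `hairpin_structure`.
#' @param mirna_window_span,star_window_span 1-based inclusive window
#'   coordinates.
#' @return fraction in [0, 1].
#' @export
assess_mirna_star_duplex <- function(structure, mirna_window_span,
                                     star_window_span) {
  m <- as.integer(mirna_window_span)
  s <- as.integer(star_window_span)
  L <- nchar(structure$window_seq)
  if (any(c(m, s) < 1L) || any(c(m, s) > L)) {
    stop("assess_mirna_star_duplex: span outside window")
  }
  if (m[1] <= s[2] && s[1] <= m[2]) {
    stop("assess_mirna_star_duplex: miRNA and star spans overlap")
  }
  partner <- rep(NA_integer_, L)
  partner[structure$pairs$i] <- structure$pairs$j
  partner[structure$pairs$j] <- structure$pairs$i
  mpos <- m[1]:m[2]
  hit <- !is.na(partner[mpos]) & partner[mpos] >= s[1] & partner[mpos] <= s[2]
  sum(hit) / length(mpos)
}

#' Fold the precursor window around a miRNA and assess the duplex
#'
#' Convenience composition of [extract_window()], [fold_mfe()] and
#' [assess_mirna_star_duplex()].
#'
#' @inheritParams extract_window
#' @param star_span optional star-strand span (precursor coordinates).
#' @param model an [load_energy_model()] object.
#' @param max_len window-length cap passed to [fold_mfe()].
#' @return a `hairpin_structure` with window offset, spans (window
#'   coordinates) and `duplex_paired_fraction` filled (NA without a star
#'   span, or when the star falls outside the window).
#' @export
fold_precursor <- function(precursor, mirna_span, star_span = NULL,
                           flank = 120L, model = load_energy_model(),
                           max_len = 1000L) {
  w <- extract_window(precursor, mirna_span, flank)
  st <- fold_mfe(w$window_seq, model, max_len)
  st$window_offset <- w$window_offset
  st$mirna_window_span <- w$mirna_window_span
  if (!is.null(star_span)) {
    sw <- as.integer(star_span) - w$window_offset + 1L
    if (sw[1] >= 1L && sw[2] <= nchar(w$window_seq)) {
      st$star_window_span <- sw
      st$duplex_paired_fraction <-
        assess_mirna_star_duplex(st, st$mirna_window_span, sw)
    }
  }
  st
}

#' Write a folded structure as a Vienna-style text block
#'
#' Header line, sequence line, dot-bracket line with the energy appended
#' as `( dG )`.
#'
#' @param structure a `hairpin_structure`. @param path output path.
#' @param id header identifier.
#' @export
write_vienna <- function(structure, path, id = "window") {
  writeLines(c(paste0(">", id), structure$window_seq,
               sprintf("%s (%7.2f)", structure$dot_bracket,
                       structure$mfe)), path)
  invisible(path)
}
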