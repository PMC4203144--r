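# MIR gene architecture: ordered exon/intron segments with miRNA/miRNA*
# spans in 1-based inclusive gene coordinates (numbering starts at the
# first nucleotide of the gene). Splice isoforms are subsets of retained
# introns; an isoform keeps the miRNA hairpin iff the segment hosting the
# miRNA (and the star) survives splicing.

#' Construct a MIR gene model
#'
#' @param gene_id identifier, e.g. `"MIR160a"`.
#' @param segments data.frame with columns `kind` (`"exon"`/`"intron"`)
#'   and `length` (bp), in gene order.
#' @param mirna_span,star_span integer length-2 vectors, 1-based inclusive
#'   gene coordinates of the mature miRNA and the star strand.
#' @param mirna_seq,star_seq optional RNA sequences (5'->3'); when given,
#'   their lengths must equal the span widths.
#' @param gene_length optional; checked against `sum(segments$length)`.
#' @return object of class `mir_gene_model`.
#' @export
mir_gene_model <- function(gene_id, segments, mirna_span, star_span = NULL,
                           mirna_seq = NULL, star_seq = NULL,
                           gene_length = NULL) {
  stopifnot(is.data.frame(segments), all(c("kind", "length") %in%
                                           names(segments)))
  if (!all(segments$kind %in% c("exon", "intron"))) {
    stop("segment kind must be 'exon' or 'intron'")
  }
  if (any(segments$length < 1L)) stop("segment lengths must be positive")
  total <- sum(segments$length)
  if (!is.null(gene_length) && total != gene_length) {
    stop("model validation error: segment lengths sum to ", total,
         " but gene_length is ", gene_length)
  }
  m <- structure(list(gene_id = gene_id, gene_length = total,
                      segments = segments[, c("kind", "length")],
                      mirna_span = as.integer(mirna_span),
                      star_span = if (!is.null(star_span))
                        as.integer(star_span),
                      mirna_seq = mirna_seq, star_seq = star_seq),
                 class = "mir_gene_model")
  chk <- check_model(m)
  hard <- !grepl("seq_length_matches_span", chk$check)
  if (!all(chk$pass[hard])) {
    stop("model validation error for ", gene_id, ": ",
         paste(chk$check[hard & !chk$pass], collapse = "; "))
  }
  if (!all(chk$pass)) {
    # published catalogues occasionally print spans and sequences that
    # disagree by a nucleotide; keep the values, surface the discrepancy
    warning("model ", gene_id, ": ",
            paste(chk$check[!chk$pass], collapse = "; "),
            " (kept; see validate_models())", call. = FALSE)
  }
  m
}

#' @export
print.mir_gene_model <- function(x, ...) {
  cat("<mir_gene_model>", x$gene_id, "-", x$gene_length, "bp;",
      sum(x$segments$kind == "exon"), "exon(s),",
      sum(x$segments$kind == "intron"), "intron(s); miRNA ",
      paste(x$mirna_span, collapse = "-"), "\n")
  invisible(x)
}

#' Coordinate map of a MIR gene model
#'
#' Cumulative 1-based inclusive spans for every segment, covering
#' `[1, gene_length]` contiguously; exons and introns are indexed 1..n
#' each within their own kind.
#'
#' @param model a [mir_gene_model()].
#' @return data.frame with `kind`, `index`, `start`, `end`.
#' @export
build_coordinate_map <- function(model) {
  seg <- model$segments
  end <- cumsum(seg$length)
  start <- end - seg$length + 1L
  idx <- stats::ave(seq_len(nrow(seg)), seg$kind, FUN = seq_along)
  data.frame(kind = seg$kind, index = as.integer(idx),
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Locate a feature span within the segment map
#'
#' Reports the unique segment fully containing the span. A span crossing
#' an exon/intron boundary is a first-class `"junction-spanning"` outcome
#' (needed by splice-isoform reasoning), never silently assigned.
#'
#' @param model a [mir_gene_model()].
#' @param span integer length-2, 1-based inclusive gene coordinates.
#' @return list with `kind` (`"exon"`, `"intron"` or
#'   `"junction-spanning"`), `index` (NA when junction-spanning) and
#'   `segment_span`.
#' @export
locate_feature <- function(model, span) {
  span <- as.integer(span)
  if (span[1] < 1L || span[2] > model$gene_length || span[1] > span[2]) {
    stop("coordinate error: span ", span[1], "-", span[2],
         " outside gene [1, ", model$gene_length, "]")
  }
  map <- build_coordinate_map(model)
  hit <- which(map$start <= span[1] & map$end >= span[2])
  if (length(hit) == 1L) {
    list(kind = map$kind[hit], index = map$index[hit],
         segment_span = c(map$start[hit], map$end[hit]))
  } else {
    first <- which(map$start <= span[1] & map$end >= span[1])
    list(kind = "junction-spanning", index = NA_integer_,
         segment_span = c(map$start[first],
                          map$end[which(map$start <= span[2] &
                                          map$end >= span[2])]))
  }
}

#' Enumerate splice isoforms of a MIR gene
#'
#' All 2^n subsets of retained introns, one isoform each. Isoforms are
#' lettered in order of decreasing retained-intron count, starting with
#' the unspliced transcript as isoform A; ties (equal retained counts)
#' order by the retained-set lexicographically. An isoform retains the
#' miRNA hairpin iff the segment containing the miRNA span (and likewise
#' the star span, when present) is an exon or a retained intron; a
#' junction-spanning miRNA never survives splicing of either flanking
#' segment.
#'
#' @param model a [mir_gene_model()].
#' @param max_introns combinatorial guard (default 12): refuse models with
#'   more introns.
#' @return data.frame with `isoform_id`, `retained_introns`
#'   (comma-separated indices, "" = all spliced), `n_retained`,
#'   `spliced_length`, `retains_mirna_hairpin`.
#' @export
enumerate_splice_isoforms <- function(model, max_introns = 12L) {
  map <- build_coordinate_map(model)
  introns <- map[map$kind == "intron", , drop = FALSE]
  n <- nrow(introns)
  if (n > max_introns) {
    stop("enumerate_splice_isoforms: ", n, " introns exceeds the cap of ",
         max_introns, " (2^n isoforms); raise max_introns deliberately")
  }
  loc_m <- locate_feature(model, model$mirna_span)
  loc_s <- if (!is.null(model$star_span)) {
    locate_feature(model, model$star_span)
  }
  subsets <- if (n == 0L) list(integer(0)) else {
    unlist(lapply(0:n, function(k) {
      if (k == 0L) list(integer(0)) else
        lapply(seq_len(ncol(utils::combn(n, k))), function(j)
          utils::combn(n, k)[, j])
    }), recursive = FALSE)
  }
  retains <- function(loc, retained) {
    if (is.null(loc)) return(TRUE)
    if (loc$kind == "exon") return(TRUE)
    if (loc$kind == "intron") return(loc$index %in% retained)
    FALSE  # junction-spanning: splicing either neighbor destroys it
  }
  rows <- lapply(subsets, function(keep) {
    removed <- setdiff(seq_len(n), keep)
    data.frame(
      retained_introns = paste(keep, collapse = ","),
      n_retained = length(keep),
      spliced_length = model$gene_length -
        sum(introns$end[removed] - introns$start[removed] + 1L),
      retains_mirna_hairpin = retains(loc_m, keep) && retains(loc_s, keep),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_retained, out$retained_introns), , drop = FALSE]
  out <- cbind(isoform_id = make_isoform_ids(nrow(out)), out)
  rownames(out) <- NULL
  out
}

# A, B, ..., Z, AA, AB, ... labels
make_isoform_ids <- function(k) {
  if (k <= 26L) return(LETTERS[seq_len(k)])
  c(LETTERS, as.vector(t(outer(LETTERS, LETTERS, paste0))))[seq_len(k)]
}

# single-model invariant checks (report rows)
check_model <- function(m) {
  checks <- list()
  add <- function(name, ok) checks[[length(checks) + 1L]] <<-
    data.frame(check = name, pass = ok, stringsAsFactors = FALSE)
  seg <- m$segments
  add("segment_lengths_sum_to_gene_length",
      sum(seg$length) == m$gene_length)
  k <- seg$kind
  alternating <- all(k[-1] != k[-length(k)])
  both <- length(unique(k)) == 2L
  add("segments_alternate",
      alternating && (!both || (k[1] == "exon" && k[length(k)] == "exon")))
  span_ok <- function(sp) !is.null(sp) && sp[1] >= 1L && sp[2] >= sp[1] &&
    sp[2] <= m$gene_length
  add("mirna_span_within_gene", span_ok(m$mirna_span))
  if (!is.null(m$star_span)) add("star_span_within_gene",
                                 span_ok(m$star_span))
  if (!is.null(m$mirna_seq)) {
    add("mirna_seq_length_matches_span",
        nchar(m$mirna_seq) == m$mirna_span[2] - m$mirna_span[1] + 1L)
  }
  if (!is.null(m$star_seq) && !is.null(m$star_span)) {
    add("star_seq_length_matches_span",
        nchar(m$star_seq) == m$star_span[2] - m$star_span[1] + 1L)
  }
  do.call(rbind, checks)
}

#' Validate a list of MIR gene models
#'
#' Report-only consistency suite: per gene, every structural invariant
#' (segment sums, alternation, span bounds, sequence-length/span-width
#' agreement) with a pass/fail flag.
#'
#' @param models list of [mir_gene_model()] objects.
#' @return data.frame with `gene_id`, `check`, `pass`.
#' @export
validate_models <- function(models) {
  if (length(models) == 0L) {
    return(data.frame(gene_id = character(), check = character(),
                      pass = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(models, function(m) {
    cbind(gene_id = m$gene_id, check_model(m))
  }))
}

#' Write MIR gene models as GFF3
#'
#' One `gene` feature per model plus `exon`, `intron`, `miRNA` and
#' `miRNA_star` children, 1-based inclusive coordinates (GFF3 dialect).
#'
#' @param models list of [mir_gene_model()].
#' @param path output path.
#' @export
write_models_gff3 <- function(models, path) {
  grs <- lapply(models, function(m) {
    map <- build_coordinate_map(m)
    feat <- data.frame(
      type = c("gene", map$kind, "miRNA",
               if (!is.null(m$star_span)) "miRNA_star"),
      start = c(1L, map$start, m$mirna_span[1],
                if (!is.null(m$star_span)) m$star_span[1]),
      end = c(m$gene_length, map$end, m$mirna_span[2],
              if (!is.null(m$star_span)) m$star_span[2]),
      ID = c(m$gene_id,
             paste0(m$gene_id, ":", map$kind, map$index),
             paste0(m$gene_id, ":miRNA"),
             if (!is.null(m$star_span)) paste0(m$gene_id, ":miRNA_star")),
      stringsAsFactors = FALSE)
    GenomicRanges::GRanges(
      seqnames = m$gene_id,
      ranges = IRanges::IRanges(feat$start, feat$end),
      strand = "+", type = feat$type, ID = feat$ID,
      Parent = ifelse(feat$type == "gene", NA_character_, m$gene_id))
  })
  gr <- suppressWarnings(do.call(c, unname(grs)))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write/read the compact gene-model TSV
#'
#' One row per gene: id, length, comma-separated exon and intron lengths,
#' miRNA/star spans and sequences. Mirrors the structure-table layout used
#' for MIR gene catalogues.
#'
#' @param models list of [mir_gene_model()]. @param path file path.
#' @export
write_models_tsv <- function(models, path) {
  df <- do.call(rbind, lapply(models, function(m) {
    seg <- m$segments
    data.frame(
      gene_id = m$gene_id, gene_length = m$gene_length,
      exon_lengths = paste(seg$length[seg$kind == "exon"], collapse = ","),
      intron_lengths = paste(seg$length[seg$kind == "intron"],
                             collapse = ","),
      mirna_start = m$mirna_span[1], mirna_end = m$mirna_span[2],
      star_start = if (!is.null(m$star_span)) m$star_span[1] else NA,
      star_end = if (!is.null(m$star_span)) m$star_span[2] else NA,
      mirna_seq = if (!is.null(m$mirna_seq)) m$mirna_seq else "",
      star_seq = if (!is.null(m$star_seq)) m$star_seq else "",
      stringsAsFactors = FALSE)
  }))
  write_tsv(df, path)
}

#' @rdname write_models_tsv
#' @return `read_models_tsv()`: list of [mir_gene_model()].
#' @export
read_models_tsv <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "gene_length", "exon_lengths",
                                 "intron_lengths", "mirna_start",
                                 "mirna_end"))
  lapply(seq_len(nrow(df)), function(i) {
    ex <- as.integer(strsplit(df$exon_lengths[i], ",")[[1]])
    iv <- if (nzchar(df$intron_lengths[i])) {
      as.integer(strsplit(df$intron_lengths[i], ",")[[1]])
    } else integer(0)
    segs <- interleave_segments(ex, iv)
    mir_gene_model(
      gene_id = df$gene_id[i], segments = segs,
      mirna_span = c(df$mirna_start[i], df$mirna_end[i]),
      star_span = if (!is.na(df$star_start[i]))
        c(df$star_start[i], df$star_end[i]),
      mirna_seq = if (nzchar(df$mirna_seq[i])) df$mirna_seq[i],
      star_seq = if (nzchar(df$star_seq[i])) df$star_seq[i],
      gene_length = df$gene_length[i])
  })
}

#' Interleave exon and intron lengths into a segment table
#'
#' Builds the ordered segment data.frame (exon1, intron1, exon2, ...)
#' used by [mir_gene_model()]; requires one more exon than introns when
#' introns are present.
#'
#' @param exon_lengths,intron_lengths integer vectors of lengths (bp).
#' @return data.frame with `kind`, `length`.
#' @export
interleave_segments <- function(exon_lengths, intron_lengths) {
  ne <- length(exon_lengths); ni <- length(intron_lengths)
  if (ni > 0L && ne != ni + 1L) {
    stop("need one more exon than introns (", ne, " exons, ", ni,
         " introns)")
  }
  kind <- if (ni == 0L) rep("exon", ne) else {
    c(rbind(rep("exon", ni), rep("intron", ni)), "exon")
  }
  len <- if (ni == 0L) exon_lengths else {
    c(rbind(exon_lengths[seq_len(ni)], intron_lengths), exon_lengths[ne])
  }
  data.frame(kind = kind, length = as.integer(len),
             stringsAsFactors = FALSE)
}
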