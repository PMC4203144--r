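# Synthetic stand-ins for the study material, used to exercise every
# analysis stage with known ground truth: transcripts with planted target
# sites of controlled mismatch/G:U composition, degradome tag pileups
# with a peak at the canonical cleavage position over Poisson background,
# MIR gene models with designed embedded hairpins, and replicated Ct
# tables with known fold changes. Every generator is a deterministic
# function of its arguments and the mandatory seed.

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) stop("seed is mandatory")
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

random_rna <- function(len, p = rep(0.25, 4)) {
  paste(sample(RNA_BASES, len, replace = TRUE, prob = p), collapse = "")
}

# target-window base that is a mismatch against miRNA base b (not WC, not
# wobble)
mm_partner <- function(b) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")[b]
  wob <- c(A = "", C = "", G = "U", U = "G")[b]
  sample(setdiff(RNA_BASES, c(comp, wob)), 1L)
}

#' Specification of one planted target site
#'
#' @param n_mm number of mismatch columns.
#' @param n_gu number of G:U wobble columns.
#' @param mm_positions optional miRNA positions (1 = 5' end) for the
#'   mismatches; sampled when `NULL`.
#' @param gu_positions optional miRNA positions for the wobbles; sampled
#'   from positions where the miRNA base is G or U.
#' @return a `site_spec` list.
#' @export
site_spec <- function(n_mm = 0L, n_gu = 0L, mm_positions = NULL,
                      gu_positions = NULL) {
  structure(list(n_mm = as.integer(n_mm), n_gu = as.integer(n_gu),
                 mm_positions = mm_positions, gu_positions = gu_positions),
            class = "site_spec")
}

# build a target window realizing the spec against `mirna`; returns
# list(window, mm_positions, gu_positions)
build_site <- function(mirna, spec) {
  L <- nchar(mirna)
  m <- strsplit(mirna, "", fixed = TRUE)[[1]]
  w <- rev(strsplit(reverse_complement(mirna), "", fixed = TRUE)[[1]])
  # w[i] (indexed by miRNA position) currently = complement of m[i]
  mm <- spec$mm_positions
  if (is.null(mm) && spec$n_mm > 0L) {
    mm <- sort(sample(seq_len(L), spec$n_mm))
  }
  mm <- as.integer(mm)
  if (length(mm) != spec$n_mm || any(mm < 1L | mm > L)) {
    stop("build_site: mm_positions inconsistent with n_mm or miRNA length")
  }
  gu <- spec$gu_positions
  if (is.null(gu) && spec$n_gu > 0L) {
    elig <- setdiff(which(m %in% c("G", "U")), mm)
    if (length(elig) < spec$n_gu) {
      stop("build_site: not enough G/U miRNA positions for ", spec$n_gu,
           " wobbles")
    }
    gu <- sort(sample(elig, spec$n_gu))
  }
  gu <- as.integer(gu)
  if (length(gu) != spec$n_gu || length(intersect(gu, mm)) > 0L) {
    stop("build_site: gu_positions inconsistent")
  }
  for (i in mm) w[i] <- mm_partner(m[i])
  for (i in gu) {
    if (!m[i] %in% c("G", "U")) stop("build_site: no wobble at ", m[i])
    w[i] <- if (m[i] == "G") "U" else "G"
  }
  # window read 5'->3' on the sense strand: reverse the per-position vector
  list(window = paste(rev(w), collapse = ""),
       mm_positions = mm, gu_positions = gu)
}

#' Generate a transcriptome with planted miRNA target sites
#'
#' Each transcript carries at most one planted site obtained by mutating
#' the reverse complement of the miRNA per its [site_spec()]; the
#' background is i.i.d. uniform ACGU, rejection-sampled so that no window
#' other than the planted one survives the scanner's discard rules.
#'
#' @param mirna miRNA sequence (5'->3', ACGU).
#' @param n_transcripts number of transcripts.
#' @param transcript_length length of each transcript (nt).
#' @param site_specs list of length `n_transcripts`; each element a
#'   [site_spec()] or `NULL` for a site-free decoy transcript.
#' @param seed mandatory RNG seed.
#' @param config [scan_config()] used for the off-target screen.
#' @param max_retries rejection-sampling cap per transcript.
#' @param site_positions optional integer vector (length
#'   `n_transcripts`) of fixed site start positions; `NA` entries are
#'   drawn uniformly. Useful to keep downstream degradome tags clear of
#'   the 3' end.
#' @return list with `transcripts` (named character vector) and `truth`
#'   (data.frame: `target_id`, `has_site`, `start`, `end`, `n_mm`,
#'   `n_gu`, `total_score`, `seed12_score`, `cleavage_position`).
#' @export
make_target_transcriptome <- function(mirna, n_transcripts = 5L,
                                      transcript_length = 1000L,
                                      site_specs = NULL, seed,
                                      config = scan_config(),
                                      max_retries = 50L,
                                      site_positions = NULL) {
  L <- nchar(mirna)
  if (transcript_length < L) stop("transcripts shorter than the miRNA")
  if (is.null(site_specs)) {
    site_specs <- rep(list(site_spec()), n_transcripts)
  }
  stopifnot(length(site_specs) == n_transcripts)
  if (n_transcripts == 0L) {
    return(list(transcripts = character(0),
                truth = data.frame(target_id = character(),
                                   has_site = logical(),
                                   start = integer(), end = integer(),
                                   n_mm = integer(), n_gu = integer(),
                                   total_score = numeric(),
                                   seed12_score = numeric(),
                                   cleavage_position = integer(),
                                   stringsAsFactors = FALSE)))
  }
  with_seed(seed, {
    seqs <- character(n_transcripts)
    truth <- vector("list", n_transcripts)
    for (t in seq_len(n_transcripts)) {
      id <- sprintf("synth_tx_%02d", t)
      spec <- site_specs[[t]]
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        s <- random_rna(transcript_length)
        if (!is.null(spec)) {
          pos <- if (!is.null(site_positions) &&
                     !is.na(site_positions[t])) {
            as.integer(site_positions[t])
          } else {
            sample(seq_len(transcript_length - L + 1L), 1L)
          }
          if (pos < 1L || pos > transcript_length - L + 1L) {
            stop("make_target_transcriptome: site position out of range")
          }
          site <- build_site(mirna, spec)
          substr(s, pos, pos + L - 1L) <- site$window
          sc <- score_site(mirna, site$window)
          survives <- !.discard(sc$total_score, sc$seed12_score, config)
        }
        hits <- suppressMessages(
          scan_transcript(mirna, s, config, target_id = id))
        extra <- if (is.null(spec)) nrow(hits) else
          sum(hits$start != pos)
        planted_ok <- is.null(spec) || !survives || any(hits$start == pos)
        if (extra == 0L && planted_ok) { ok <- TRUE; break }
      }
      if (!ok) {
        stop("make_target_transcriptome: rejection sampling exceeded ",
             max_retries, " retries; use a longer miRNA or shorter ",
             "transcripts")
      }
      seqs[t] <- s
      truth[[t]] <- if (is.null(spec)) {
        data.frame(target_id = id, has_site = FALSE, start = NA_integer_,
                   end = NA_integer_, n_mm = NA_integer_,
                   n_gu = NA_integer_, total_score = NA_real_,
                   seed12_score = NA_real_,
                   cleavage_position = NA_integer_,
                   stringsAsFactors = FALSE)
      } else {
        sc <- score_site(mirna, site$window)
        data.frame(target_id = id, has_site = TRUE, start = pos,
                   end = pos + L - 1L, n_mm = spec$n_mm,
                   n_gu = spec$n_gu, total_score = sc$total_score,
                   seed12_score = sc$seed12_score,
                   cleavage_position = pos + L - 1L - 9L,
                   stringsAsFactors = FALSE)
      }
      names(seqs)[t] <- id
    }
    list(transcripts = seqs, truth = do.call(rbind, truth))
  })
}

#' Generate a degradome tag library over a synthetic transcriptome
#'
#' For every planted site, `signal_reads` tags whose 5' ends sit at the
#' site's expected cleavage position; plus Poisson(`background_rate`)
#' tags at every transcript position. Tag sequences are copied from the
#' transcript starting at the 5'-end position; tags running past the 3'
#' end are truncated and flagged.
#'
#' @param truth truth table from [make_target_transcriptome()].
#' @param transcripts named character vector of transcript sequences.
#' @param signal_reads reads planted at each cleavage position.
#' @param background_rate Poisson mean per position (reads/position).
#' @param tag_len tag length in nt (26 or 27; may alternate by drawing
#'   from the vector).
#' @param seed mandatory RNG seed.
#' @return data.frame with `tag_seq`, `count`, `truncated`.
#' @export
make_degradome_library <- function(truth, transcripts, signal_reads = 50L,
                                   background_rate = 1.0,
                                   tag_len = c(26L, 27L), seed) {
  with_seed(seed, {
    emit <- function(tx, pos, count) {
      tl <- if (length(tag_len) > 1L) {
        sample(tag_len, length(pos), replace = TRUE)
      } else rep(tag_len, length(pos))
      s <- substr(rep(tx, length(pos)), pos, pos + tl - 1L)
      data.frame(tag_seq = s, count = count, truncated = nchar(s) < tl,
                 stringsAsFactors = FALSE)
    }
    rows <- list()
    for (k in seq_len(nrow(truth))) {
      if (!isTRUE(truth$has_site[k])) next
      tx <- transcripts[[truth$target_id[k]]]
      rows[[length(rows) + 1L]] <-
        emit(tx, truth$cleavage_position[k], signal_reads)
    }
    if (background_rate > 0) {
      for (id in names(transcripts)) {
        tx <- transcripts[[id]]
        draws <- stats::rpois(nchar(tx), background_rate)
        hit <- which(draws > 0L)
        if (length(hit)) {
          rows[[length(rows) + 1L]] <- emit(tx, hit, draws[hit])
        }
      }
    }
    if (length(rows) == 0L) {
      return(data.frame(tag_seq = character(), count = integer(),
                        truncated = logical(), stringsAsFactors = FALSE))
    }
    df <- do.call(rbind, rows)
    agg <- stats::aggregate(cbind(count = df$count),
                            by = list(tag_seq = df$tag_seq,
                                      truncated = df$truncated), FUN = sum)
    agg <- agg[order(agg$tag_seq), c("tag_seq", "count", "truncated")]
    rownames(agg) <- NULL
    agg
  })
}

#' Generate a MIR gene model with a designed embedded hairpin
#'
#' The hairpin is miRNA arm + loop + star arm, with the star arm the
#' reverse complement of the first `stem_len - 2` miRNA nucleotides
#' followed by 2 unpaired nucleotides (the 2-nt 3'-overhang geometry of
#' miRNA/miRNA* duplexes); it is embedded at a random offset inside the
#' chosen exon or intron of a random-background gene.
#'
#' @param exon_lengths,intron_lengths segment lengths in gene order
#'   (one more exon than introns unless intronless).
#' @param host_kind,host_index which segment receives the hairpin.
#' @param stem_len miRNA length (>= 15; default 21).
#' @param loop_len nucleotides between the arms (default 6).
#' @param gc high-GC miRNA arm fraction (default 0.7; a strong stem makes
#'   the designed fold the unambiguous optimum).
#' @param seed mandatory RNG seed.
#' @return list with `model` (a [mir_gene_model()]) and `precursor`
#'   (the gene/pri-miRNA sequence).
#' @export
make_mir_gene <- function(exon_lengths, intron_lengths = integer(0),
                          host_kind = "exon", host_index = 1L,
                          stem_len = 21L, loop_len = 6L, gc = 0.7,
                          seed) {
  if (stem_len < 15L) stop("make_mir_gene: stem_len must be >= 15")
  segs <- interleave_segments(exon_lengths, intron_lengths)
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
    mirna <- random_rna(stem_len, p)
    star <- paste0(reverse_complement(substr(mirna, 1L, stem_len - 2L)),
                   random_rna(2L))
    hairpin <- paste0(mirna, random_rna(loop_len), star)
    hlen <- nchar(hairpin)
    end <- cumsum(segs$length)
    start <- end - segs$length + 1L
    idx <- stats::ave(seq_len(nrow(segs)), segs$kind, FUN = seq_along)
    host <- which(segs$kind == host_kind & idx == host_index)
    if (length(host) != 1L) stop("make_mir_gene: no segment ", host_kind,
                                 " ", host_index)
    if (segs$length[host] < hlen) {
      stop("make_mir_gene: hairpin (", hlen,
           " nt) longer than host segment (", segs$length[host], " nt)")
    }
    gene <- random_rna(sum(segs$length))
    off <- sample(seq.int(start[host], end[host] - hlen + 1L), 1L)
    substr(gene, off, off + hlen - 1L) <- hairpin
    model <- mir_gene_model(
      gene_id = sprintf("synthMIR_%s%d", host_kind, host_index),
      segments = segs,
      mirna_span = c(off, off + stem_len - 1L),
      star_span = c(off + stem_len + loop_len,
                    off + stem_len + loop_len + nchar(star) - 1L),
      mirna_seq = mirna, star_seq = star)
    list(model = model, precursor = gene)
  })
}

#' Generate a replicated Ct table with a known fold change
#'
#' Control dCt ~ Normal(0, `noise_sd_ct`); heat dCt ~
#' Normal(-log2(`true_fold`), `noise_sd_ct`): Ct noise is applied on the
#' cycle scale (instrument-like), so fold-change noise is log-normal.
#' The reference Ct is held at `ct_reference`.
#'
#' @param gene_id identifier.
#' @param true_fold true heat/control expression ratio (> 0).
#' @param noise_sd_ct SD of the Ct noise, cycles.
#' @param n_reps biological replicates per condition (default 3).
#' @param timepoints hours (default 24).
#' @param ct_reference reference-gene Ct (default 20).
#' @param seed mandatory RNG seed.
#' @return Ct data.frame (columns of [read_ct_table()]).
#' @export
make_ct_table <- function(gene_id = "synth_gene", true_fold = 13,
                          noise_sd_ct = 0.1, n_reps = 3L,
                          timepoints = 24, ct_reference = 20, seed) {
  if (true_fold <= 0) stop("true_fold must be > 0")
  with_seed(seed, {
    rows <- list()
    for (tp in timepoints) {
      for (cond in c("control", "heat")) {
        mu <- if (cond == "control") 0 else -log2(true_fold)
        d <- stats::rnorm(n_reps, mu, noise_sd_ct)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gene_id, condition = cond, timepoint = tp,
          replicate = seq_len(n_reps),
          ct_target = ct_reference + d,
          ct_reference = ct_reference, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
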