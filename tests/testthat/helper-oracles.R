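# Independent oracles used to cross-check the package implementations.
# Each is written from the model definition directly (per-position
# recounts, brute-force loops, exhaustive enumeration) and shares no code
# with the functions it checks.

oracle_random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# per-position recount of the mismatch scoring for one window
oracle_score_window <- function(mirna, window) {
  L <- nchar(mirna)
  total <- 0
  seed <- 0
  for (i in seq_len(L)) {
    mb <- substr(mirna, i, i)
    tb <- substr(window, L - i + 1L, L - i + 1L)
    duo <- paste0(mb, tb)
    pts <- if (duo %in% c("AU", "UA", "GC", "CG")) 0
    else if (duo %in% c("GU", "UG")) 0.5
    else 1
    total <- total + pts
    if (i <= 12L) seed <- seed + pts
  }
  c(total = total, seed = seed)
}

# all-windows brute force of the scanner's surviving start positions
oracle_scan_survivors <- function(mirna, transcript,
                                  max_total = 4, max_seed = 2.5,
                                  combination = "either") {
  L <- nchar(mirna)
  n <- nchar(transcript) - L + 1L
  if (n < 1L) return(integer(0))
  keep <- integer(0)
  for (s in seq_len(n)) {
    w <- substr(transcript, s, s + L - 1L)
    if (grepl("N", w, fixed = TRUE)) next
    sc <- oracle_score_window(mirna, w)
    drop <- if (combination == "either") {
      sc["total"] >= max_total || sc["seed"] > max_seed
    } else {
      sc["total"] >= max_total && sc["seed"] > max_seed
    }
    if (!drop) keep <- c(keep, s)
  }
  keep
}

# brute-force nearest-neighbor summation for an ungapped duplex
oracle_duplex_dg <- function(mirna, window, model) {
  L <- nchar(mirna)
  pn <- character(L)
  for (i in seq_len(L)) {
    duo <- paste0(substr(mirna, i, i),
                  substr(window, L - i + 1L, L - i + 1L))
    pn[i] <- if (duo %in% rownames(model$stack)) duo else NA
  }
  dg <- model$duplex_init + model$mismatch_penalty * sum(is.na(pn))
  for (i in seq_len(L - 1L)) {
    if (!is.na(pn[i]) && !is.na(pn[i + 1L])) {
      dg <- dg + model$stack[pn[i], pn[i + 1L]]
    }
  }
  idx <- which(!is.na(pn))
  if (length(idx)) {
    for (e in unique(c(idx[1], idx[length(idx)]))) {
      if (pn[e] %in% c("AU", "UA", "GU", "UG")) dg <- dg + model$terminal_au
    }
  }
  dg
}

oracle_can_pair <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

# Nussinov base-pair maximization, minimum hairpin loop 3
oracle_nussinov <- function(seq) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(b)
  if (n < 5L) return(0L)
  N <- matrix(0L, n, n)
  for (span in 4:(n - 1)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- N[i, j - 1]
      ks <- i:(j - 4)
      ks <- ks[oracle_can_pair(b[ks], b[j])]
      for (k in ks) {
        left <- if (k > i) N[i, k - 1] else 0L
        inner <- if (k + 1 <= j - 1) N[k + 1, j - 1] else 0L
        cand <- left + inner + 1L
        if (cand > best) best <- cand
      }
      N[i, j] <- best
    }
  }
  N[1, n]
}

# loop-decomposition rescoring of a structure under the folding model;
# returns Inf for structures the model excludes (interior loops whose
# total unpaired length exceeds max_loop)
oracle_structure_energy <- function(seq, pairs, model) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(b)
  lookup <- function(tab, len) {
    if (len <= length(tab)) tab[len]
    else tab[length(tab)] + model$loop_extrap_slope * (len - length(tab))
  }
  if (nrow(pairs) == 0L) return(0)
  partner <- rep(NA_integer_, n)
  partner[pairs$i] <- pairs$j
  partner[pairs$j] <- pairs$i
  pt <- function(i, j) paste0(b[i], b[j])
  total <- model$pair_bonus * nrow(pairs)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    kids <- list(); unpaired <- 0L; k <- i + 1L
    while (k < j) {
      if (!is.na(partner[k]) && partner[k] > k) {
        kids[[length(kids) + 1L]] <- c(k, partner[k])
        k <- partner[k] + 1L
      } else {
        unpaired <- unpaired + 1L
        k <- k + 1L
      }
    }
    if (length(kids) == 0L) {
      total <- total + lookup(model$hairpin, j - i - 1L)
    } else if (length(kids) == 1L) {
      a <- kids[[1]][1]; d <- kids[[1]][2]
      l1 <- a - i - 1L; l2 <- j - d - 1L
      if (l1 == 0L && l2 == 0L) {
        total <- total + model$stack[pt(i, j), pt(a, d)]
      } else if (l1 + l2 > model$max_loop) {
        return(Inf)
      } else if (l1 == 0L || l2 == 0L) {
        total <- total + lookup(model$bulge, l1 + l2)
      } else {
        total <- total + lookup(model$internal, l1 + l2)
      }
    } else {
      total <- total + model$ml_close +
        model$ml_branch * (length(kids) + 1L) +
        model$ml_unpaired * unpaired
    }
  }
  total
}

# exhaustive enumeration of all admissible structures; returns the
# minimum energy (0 = open chain). Exponential: keep sequences short.
oracle_exhaustive_min <- function(seq, model) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(b)
  best <- 0
  memo <- new.env(parent = emptyenv())
  structures <- function(i, j) {
    # list of pair-matrices (2-col) for segment i..j
    if (j - i < 4L) return(list(cbind(integer(0), integer(0))))
    key <- paste0(i, ":", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- structures(i + 1L, j)  # i unpaired
    for (k in (i + 4L):j) {
      if (!oracle_can_pair(b[i], b[k])) next
      inner <- structures(i + 1L, k - 1L)
      right <- if (k + 1L <= j) structures(k + 1L, j) else
        list(cbind(integer(0), integer(0)))
      for (s1 in inner) for (s2 in right) {
        out[[length(out) + 1L]] <- rbind(c(i, k), s1, s2)
      }
    }
    memo[[key]] <- out
    out
  }
  for (st in structures(1L, n)) {
    if (nrow(st) == 0L) next
    e <- oracle_structure_energy(seq, data.frame(i = st[, 1], j = st[, 2]),
                                 model)
    if (e < best) best <- e
  }
  best
}

# brute-force tag mapping: position-by-position prefix comparison
oracle_map_counts <- function(tags, transcripts, match_len = 20L) {
  counts <- lapply(transcripts, function(s) numeric(nchar(s)))
  for (k in seq_len(nrow(tags))) {
    pref <- substr(tags$tag_seq[k], 1L, match_len)
    if (nchar(pref) < match_len) next
    for (id in names(transcripts)) {
      s <- transcripts[[id]]
      for (p in seq_len(max(0L, nchar(s) - match_len + 1L))) {
        if (substr(s, p, p + match_len - 1L) == pref) {
          counts[[id]][p] <- counts[[id]][p] + tags$count[k]
        }
      }
    }
  }
  counts
}
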