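model <- load_energy_model()

test_that("window extraction does the flank arithmetic and clips", {
  pre <- oracle_random_rna(1198)
  w <- extract_window(pre, c(344, 364), flank = 120)
  expect_equal(w$window_offset, 224L)
  expect_equal(nchar(w$window_seq), 484L - 224L + 1L)
  expect_equal(w$window_seq, substr(pre, 224, 484))
  expect_equal(w$mirna_window_span, c(121L, 141L))
  w2 <- extract_window(oracle_random_rna(1000), c(5, 25), flank = 120)
  expect_equal(w2$window_offset, 1L)
  expect_equal(nchar(w2$window_seq), 145L)
  w3 <- extract_window(pre, c(344, 364), flank = 0)
  expect_equal(nchar(w3$window_seq), 21L)
  expect_error(extract_window("ACGUACGU", c(5, 20)), "coordinate error")
})

test_that("poly-A folds to the open chain at zero energy", {
  st <- fold_mfe(strrep("A", 60))
  expect_equal(nrow(st$pairs), 0L)
  expect_equal(st$mfe, 0)
  expect_equal(st$dot_bracket, strrep(".", 60))
})

test_that("windows containing N are refused", {
  expect_error(fold_mfe("ACGUNACGU"), "N")
})

test_that("a designed GC stem in AU background is recovered in full", {
  set.seed(14)
  stem <- paste(sample(c("G", "C"), 20, replace = TRUE), collapse = "")
  hp <- paste0(strrep("A", 15), stem, "GAAA",
               reverse_complement(stem), strrep("A", 15))
  st <- fold_mfe(hp)
  designed <- data.frame(i = 15L + 1:20, j = 15L + 20L + 4L + 21L - 1:20)
  got <- paste(st$pairs$i, st$pairs$j)
  expect_true(all(paste(designed$i, designed$j) %in% got))
  # and the structure is at least as good as the designed stem alone
  expect_lte(st$mfe, oracle_structure_energy(hp, designed, model))
})

test_that("dot-bracket, pair constraints and energy re-scoring agree", {
  set.seed(31)
  for (k in 1:25) {
    s <- oracle_random_rna(sample(40:120, 1))
    st <- fold_mfe(s)
    if (nrow(st$pairs)) {
      expect_true(all(st$pairs$j - st$pairs$i >= 4))   # min loop 3
      expect_equal(anyDuplicated(c(st$pairs$i, st$pairs$j)), 0L)
      # non-crossing
      for (r in seq_len(nrow(st$pairs))) {
        i <- st$pairs$i[r]; j <- st$pairs$j[r]
        inside <- st$pairs$i > i & st$pairs$i < j
        expect_true(all(st$pairs$j[inside] < j))
      }
      expect_equal(nchar(gsub("[^()]", "", st$dot_bracket)),
                   2L * nrow(st$pairs))
    }
    # MFE equals the independent loop-decomposition rescoring
    expect_equal(st$mfe, oracle_structure_energy(s, st$pairs, model),
                 tolerance = 1e-9, info = paste("seq", k))
  }
})

test_that("pair-maximization folding equals independent Nussinov counts", {
  set.seed(77)
  pm <- pair_max_model()
  for (k in 1:40) {
    s <- oracle_random_rna(sample(20:120, 1))
    st <- fold_mfe(s, pm)
    expect_equal(nrow(st$pairs), oracle_nussinov(s),
                 info = paste("seq", k))
    expect_equal(st$mfe, -oracle_nussinov(s))
  }
})

test_that("folding is optimal against exhaustive enumeration (small n)", {
  set.seed(55)
  for (k in 1:8) {
    s <- oracle_random_rna(sample(18:24, 1))
    st <- fold_mfe(s)
    expect_equal(st$mfe, oracle_exhaustive_min(s, model),
                 tolerance = 1e-9, info = paste("seq", k))
  }
})

test_that("miRNA/miRNA* duplex pairing fraction is read off the fold", {
  set.seed(9)
  stem <- paste(sample(c("G", "C"), 21, replace = TRUE), collapse = "")
  hp <- paste0(stem, "GCAAGC", reverse_complement(stem))
  st <- fold_mfe(hp)
  f <- assess_mirna_star_duplex(st, c(1, 21), c(28, 48))
  expect_equal(f, 1.0)
  open <- fold_mfe(strrep("A", 60))
  expect_equal(assess_mirna_star_duplex(open, c(1, 21), c(30, 50)), 0)
  expect_error(assess_mirna_star_duplex(st, c(1, 21), c(15, 30)),
               "overlap")
})

test_that("two designed symmetric mismatches leave 19/21 positions paired", {
  # 21-nt arms pairing arm1[i] with arm2 across a tetraloop; positions 8
  # and 14 of arm1 are mutated to unpairable partners (A across from A)
  set.seed(6)
  arm1 <- paste(sample(c("G", "C"), 21, replace = TRUE), collapse = "")
  arm2 <- reverse_complement(arm1)
  a1 <- strsplit(arm1, "")[[1]]
  a2 <- strsplit(arm2, "")[[1]]
  for (p in c(8L, 14L)) {
    a1[p] <- "A"
    a2[21L - p + 1L] <- "A"
  }
  hp <- paste0(paste(a1, collapse = ""), "GCAAGC",
               paste(a2, collapse = ""))
  st <- fold_mfe(hp)
  f <- assess_mirna_star_duplex(st, c(1, 21), c(28, 48))
  expect_equal(f, 19 / 21)
})

test_that("fold_precursor maps window coordinates and writes Vienna text", {
  set.seed(12)
  g <- make_mir_gene(exon_lengths = c(150, 120, 150),
                     intron_lengths = c(90, 260), host_kind = "intron",
                     host_index = 2L, stem_len = 21L, seed = 303L)
  st <- fold_precursor(g$precursor, g$model$mirna_span,
                       g$model$star_span, flank = 120)
  # the designed duplex pairs 19 of 21 miRNA positions (2-nt overhangs);
  # require >= 90% of the designed pairing to be recovered
  expect_gte(st$duplex_paired_fraction, 0.9 * 19 / 21)
  f <- withr::local_tempfile(fileext = ".vienna")
  write_vienna(st, f, id = "x")
  lines <- readLines(f)
  expect_equal(lines[1], ">x")
  expect_equal(lines[2], st$window_seq)
  expect_match(lines[3], "\\(\\s*-?\\d+\\.\\d+\\)$")
})

test_that("windows beyond the length cap are refused", {
  expect_error(fold_mfe(strrep("A", 80), max_len = 50L), "cap")
})
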