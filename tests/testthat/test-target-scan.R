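test_that("pair classification follows WC / wobble / mismatch rules", {
  expect_equal(classify_pair("G", "C"), "WC")
  expect_equal(classify_pair("G", "U"), "GU")
  expect_equal(classify_pair("U", "G"), "GU")
  expect_equal(classify_pair("A", "A"), "MM")
  expect_equal(classify_pair(c("A", "C"), c("U", "C")), c("WC", "MM"))
  expect_error(classify_pair("N", "A"), "invalid base")
})

test_that("a perfect duplex scores zero; scoring matches a recount", {
  m <- "UGCCUGGCUCCCUGUAUGCCA"
  s <- score_site(m, reverse_complement(m))
  expect_equal(s$total_score, 0)
  expect_equal(s$seed12_score, 0)
  expect_equal(s$pairs, strrep("W", 21))
  set.seed(42)
  for (k in 1:50) {
    mi <- oracle_random_rna(21)
    w <- oracle_random_rna(21)
    got <- score_site(mi, w)
    exp <- oracle_score_window(mi, w)
    expect_equal(got$total_score, unname(exp["total"]))
    expect_equal(got$seed12_score, unname(exp["seed"]))
    expect_lte(got$seed12_score, got$total_score)
  }
})

test_that("score is additive: one wobble adds 0.5, one mismatch adds 1", {
  m <- strrep("G", 21)
  w0 <- reverse_complement(m)
  base <- score_site(m, w0)$total_score
  w_gu <- w0; substr(w_gu, 10, 10) <- "U"   # G:U wobble column
  expect_equal(score_site(m, w_gu)$total_score, base + 0.5)
  w_mm <- w0; substr(w_mm, 10, 10) <- "G"   # G:G mismatch column
  expect_equal(score_site(m, w_mm)$total_score, base + 1)
})

test_that("discard rules: seed > 2.5 and total >= 4 boundaries", {
  m <- strrep("G", 21)
  # 3 mismatches at miRNA positions 2, 5, 9 -> total 3.0, seed 3.0
  w <- strsplit(reverse_complement(m), "")[[1]]
  for (i in c(2, 5, 9)) w[21 - i + 1] <- "G"
  w <- paste(w, collapse = "")
  s <- score_site(m, w)
  expect_equal(s$total_score, 3.0)
  expect_equal(s$seed12_score, 3.0)
  cfg <- scan_config()
  expect_true(mirheat:::.discard(s$total_score, s$seed12_score, cfg))
  # 6 wobbles + 1 mismatch -> total 4.0: discarded by the total rule
  w2 <- strsplit(reverse_complement(m), "")[[1]]
  for (i in 13:18) w2[21 - i + 1] <- "U"
  w2[21 - 20 + 1] <- "G"
  s2 <- score_site(m, paste(w2, collapse = ""))
  expect_equal(s2$total_score, 4.0)
  expect_lte(s2$seed12_score, 2.5)
  expect_true(mirheat:::.discard(s2$total_score, s2$seed12_score, cfg))
  # under the conjunctive reading the same duplex survives
  cfg_both <- scan_config(discard_combination = "both")
  expect_false(mirheat:::.discard(s2$total_score, s2$seed12_score,
                                  cfg_both))
  # total 3.9 with seed 2.5 survives either reading
  expect_false(mirheat:::.discard(3.9, 2.5, cfg))
})

test_that("scanning finds exactly one planted perfect site", {
  set.seed(5)
  m <- oracle_random_rna(21)
  repeat {
    bg <- oracle_random_rna(300)
    tx <- paste0(substr(bg, 1, 100), reverse_complement(m),
                 substr(bg, 101, 300))
    if (length(oracle_scan_survivors(m, tx)) == 1L) break
  }
  hits <- scan_transcript(m, tx, target_id = "t")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 101L)
  expect_equal(hits$end, 121L)
  expect_equal(hits$total_score, 0)
})

test_that("poly-A transcript yields no GC-rich miRNA hits", {
  hits <- scan_transcript(strrep("G", 21), strrep("A", 200))
  expect_equal(nrow(hits), 0L)
  expect_equal(attr(hits, "windows_scanned"), 180L)
})

test_that("a transcript shorter than the miRNA warns and returns empty", {
  expect_warning(h <- scan_transcript(strrep("G", 21), "ACGU"), "shorter")
  expect_equal(nrow(h), 0L)
})

test_that("windows containing N are skipped and counted", {
  m <- strrep("G", 21)
  tx <- paste0(reverse_complement(m), "N", reverse_complement(m))
  expect_message(h <- scan_transcript(m, tx), "skipped")
  expect_equal(attr(h, "windows_skipped_n"), 21L)
  expect_equal(h$start, c(1L, 23L))
})

test_that("scanner equals the all-windows brute force on random pairs", {
  set.seed(99)
  for (k in 1:30) {
    m <- oracle_random_rna(sample(19:24, 1))
    tx <- oracle_random_rna(sample(60:300, 1))
    for (comb in c("either", "both")) {
      cfg <- scan_config(discard_combination = comb)
      got <- scan_transcript(m, tx, cfg)
      expect_equal(got$start,
                   oracle_scan_survivors(m, tx, combination = comb),
                   info = paste("case", k, comb))
      # survivors' scores equal the oracle recount
      for (r in seq_len(nrow(got))) {
        w <- substr(tx, got$start[r], got$end[r])
        expect_equal(got$total_score[r],
                     unname(oracle_score_window(m, w)["total"]))
      }
    }
  }
})

test_that("MFE filter boundary is inclusive and ranking breaks ties", {
  aln <- data.frame(
    mirna_id = "m", target_id = c("t1", "t2", "t3", "t4", "t5"),
    start = c(5L, 9L, 2L, 7L, 1L), end = c(25L, 29L, 22L, 27L, 21L),
    pairs = strrep("W", 21), total_score = c(1.0, 0.5, 1.0, 0, 0),
    seed12_score = 0, mfe = c(-18, -18, -20, -15.0, -14.9),
    rank = NA_integer_, stringsAsFactors = FALSE)
  out <- filter_and_rank(aln, scan_config())
  expect_equal(nrow(out), 4L)              # -14.9 removed, -15.0 kept
  expect_equal(out$mfe, c(-20, -18, -18, -15))
  # on the -18 tie the 0.5-score duplex ranks before the 1.0
  expect_equal(out$total_score[2:3], c(0.5, 1.0))
  expect_equal(out$rank, 1:4)
  expect_error(filter_and_rank(transform(aln, mfe = NA_real_)),
               "not populated")
})

test_that("pair strings render as run-length classes", {
  expect_equal(format_pair_string("WWWWWWWWWGWWWWWMWWWWW"),
               "WC×9,GU,WC×5,MM,WC×5")
  expect_equal(format_pair_string("W"), "WC")
})
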