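test_that("tag mapping increments the 5'-end position by the tag count", {
  set.seed(2)
  tx <- c(t1 = oracle_random_rna(800))
  tag <- substr(tx[["t1"]], 501, 527)
  tags <- data.frame(tag_seq = tag, count = 7L)
  mp <- map_tags(tags, tx)
  expect_equal(mp$counts$t1[501], 7)
  expect_equal(sum(mp$counts$t1), 7)
  expect_equal(mp$unmapped, 0)
})

test_that("unmatched tags land in the unmapped tally", {
  tx <- c(t1 = strrep("A", 200))
  tags <- data.frame(tag_seq = strrep("G", 26), count = 3L)
  mp <- map_tags(tags, tx)
  expect_equal(sum(mp$counts$t1), 0)
  expect_equal(mp$unmapped, 3)
})

test_that("multi-mapping tags hit every locus under count-to-all", {
  core <- oracle_random_rna(27)
  set.seed(4)
  tx <- c(a = paste0(oracle_random_rna(50), core, oracle_random_rna(50)),
          b = paste0(oracle_random_rna(10), core, oracle_random_rna(90)))
  tags <- data.frame(tag_seq = core, count = 5L)
  mp <- map_tags(tags, tx)
  expect_equal(mp$counts$a[51], 5)
  expect_equal(mp$counts$b[11], 5)
  expect_equal(sum(mp$assigned), 10)  # 2 loci x count under count-to-all
  expect_equal(mp$multi_tags, 1L)
  frac <- map_tags(tags, tx, multimap = "fractional")
  expect_equal(sum(frac$assigned), 5)
})

test_that("tags shorter than match_len are skipped with a warning", {
  tx <- c(t1 = strrep("A", 100))
  tags <- data.frame(tag_seq = "ACGU", count = 1L)
  expect_warning(mp <- map_tags(tags, tx), "shorter")
  expect_equal(sum(mp$counts$t1), 0)
})

test_that("mapping agrees with the brute-force string search", {
  set.seed(19)
  tx <- c(x = oracle_random_rna(400), y = oracle_random_rna(300))
  tags <- data.frame(
    tag_seq = c(substr(tx[["x"]], 101, 127), substr(tx[["y"]], 51, 76),
                oracle_random_rna(26)),
    count = c(4L, 2L, 9L))
  mp <- map_tags(tags, tx)
  oc <- oracle_map_counts(tags, tx)
  expect_equal(mp$counts$x, oc$x)
  expect_equal(mp$counts$y, oc$y)
})

test_that("t-plot mean is total reads over transcript length", {
  tp <- build_tplot(c(0, 0, 10, 0, 0), "t")
  expect_equal(tp$mean_count, 2.0)
  expect_equal(build_tplot(rep(0, 7))$mean_count, 0)
  expect_error(build_tplot(numeric(0)), "zero-length")
})

test_that("expected cleavage position is opposite miRNA position 10", {
  expect_equal(expected_cleavage_position(list(start = 101L, end = 121L)),
               112L)
  expect_equal(expected_cleavage_position(list(start = 101L, end = 122L)),
               113L)
  expect_error(
    expected_cleavage_position(list(start = 101L, end = 110L)),
    "shorter than 11")
})

test_that("cleavage categories follow the maximum/mean tiers", {
  aln <- list(start = 481L, end = 501L, mirna_id = "m")
  pos <- 492L
  counts <- rep(1, 1000)
  counts[pos] <- 50
  tp <- build_tplot(counts, "t")
  call <- call_cleavage(tp, aln)
  expect_equal(call$category, 0L)
  expect_equal(call$position, pos)
  expect_equal(call$reads, 50)
  expect_equal(call$fold_over_mean, 50 / ((50 + 999) / 1000),
               tolerance = 1e-12)

  # tied maximum elsewhere -> category 1
  counts2 <- counts; counts2[800] <- 50
  expect_equal(call_cleavage(build_tplot(counts2, "t"), aln)$category, 1L)

  # above mean but not a maximum -> category 2
  counts3 <- counts; counts3[800] <- 80
  expect_equal(call_cleavage(build_tplot(counts3, "t"), aln)$category, 2L)

  # > 1 read but at/below mean -> category 3
  counts4 <- rep(10, 1000); counts4[pos] <- 5
  counts4[pos + (-1:1)] <- c(4, 5, 3)
  expect_equal(call_cleavage(build_tplot(counts4, "t"), aln)$category, 3L)

  # empty t-plot -> category 4 with zero reads
  call0 <- call_cleavage(build_tplot(rep(0, 1000), "t"), aln)
  expect_equal(call0$category, 4L)
  expect_equal(call0$reads, 0)
})

test_that("shifting a peak beyond the tolerance degrades the category", {
  aln <- list(start = 481L, end = 501L, mirna_id = "m")
  pos <- 492L
  for (shift in 0:4) {
    counts <- rep(1, 1000)
    counts[pos + shift] <- 50
    cat_s <- call_cleavage(build_tplot(counts, "t"), aln,
                           tolerance = 1L)$category
    if (shift <= 1) expect_equal(cat_s, 0L) else expect_gte(cat_s, 2L)
  }
})

test_that("read conservation holds from tags through t-plots", {
  set.seed(33)
  m <- oracle_random_rna(21)
  sim <- make_target_transcriptome(m, n_transcripts = 2L,
                                   transcript_length = 500L, seed = 10L)
  tags <- make_degradome_library(sim$truth, sim$transcripts,
                                 signal_reads = 40L, background_rate = 0.5,
                                 seed = 11L)
  # truncated 3'-end tags shorter than match_len are skipped (warning)
  mp <- suppressWarnings(map_tags(tags, sim$transcripts))
  total_in <- sum(tags$count[!tags$truncated])
  # every full-length tag comes verbatim from one transcript position;
  # multi-mapping can only add counts
  expect_gte(sum(mp$assigned) + mp$unmapped, total_in)
  for (id in names(sim$transcripts)) {
    tp <- build_tplot(mp$counts[[id]], id)
    expect_equal(sum(tp$counts), mp$assigned[[id]])
  }
})

test_that("tag library IO round-trips in TSV and FASTA forms", {
  tags <- data.frame(tag_seq = c(strrep("ACGU", 7)[1],
                                 paste0(strrep("GA", 13), "G")),
                     count = c(3L, 8L))
  tags$tag_seq <- c(strrep("A", 26), strrep("G", 27))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(tags, f)
  back <- read_tags(f)
  expect_equal(back$count, tags$count)
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">tag1 count=3", strrep("A", 26),
               ">tag2 count=8", strrep("G", 27)), fa)
  expect_equal(read_tags(fa)$count, c(3L, 8L))
  bad <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(tag_seq = "ACGU", count = 1L), bad)
  expect_error(read_tags(bad), "length")
})

test_that("cleavage calls export as BED with read-count scores", {
  calls <- data.frame(transcript_id = "t1", mirna_id = "m",
                      position = 112L, reads = 50L, mean_count = 1.05,
                      fold_over_mean = 47.6, category = 0L)
  f <- withr::local_tempfile(fileext = ".bed")
  write_calls_bed(calls, f)
  line <- strsplit(readLines(f), "\t")[[1]]
  expect_equal(line[1:3], c("t1", "111", "112"))  # 0-based half-open
  expect_equal(line[5], "50")
})
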