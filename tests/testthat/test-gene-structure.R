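models <- suppressWarnings(barley_mir_models())

test_that("segment lengths of all catalogued genes sum to the gene length", {
  printed <- c(MIR160a = 1198, MIR166a = 1320, MIR167h = 1293,
               `MIR530-5p` = 1408, `MIR1432-5p` = 2083, MIR1120b = 2884,
               MIR5175a = 5935, MIR5203 = 6826)
  expect_setequal(names(models), names(printed))
  for (g in names(printed)) {
    expect_equal(sum(models[[g]]$segments$length), unname(printed[g]))
    expect_equal(models[[g]]$gene_length, unname(printed[g]))
  }
})

test_that("coordinate map is contiguous and cumulative", {
  map <- build_coordinate_map(models$MIR160a)
  expect_equal(map$start, c(1L, 207L, 280L, 327L, 538L, 637L, 851L))
  expect_equal(map$end, c(206L, 279L, 326L, 537L, 636L, 850L, 1198L))
  expect_equal(map$kind, c("exon", "intron", "exon", "intron", "exon",
                           "intron", "exon"))
  expect_equal(map$index, c(1L, 1L, 2L, 2L, 3L, 3L, 4L))
  for (m in models) {
    mp <- build_coordinate_map(m)
    expect_equal(mp$start[1], 1L)
    expect_equal(mp$end[nrow(mp)], m$gene_length)
    expect_true(all(mp$start[-1] == mp$end[-nrow(mp)] + 1L))
  }
})

test_that("single-exon gene maps to one full-length span", {
  m <- mir_gene_model("g", data.frame(kind = "exon", length = 500L),
                      mirna_span = c(10, 30))
  expect_equal(build_coordinate_map(m),
               data.frame(kind = "exon", index = 1L, start = 1L,
                          end = 500L, stringsAsFactors = FALSE))
})

test_that("inconsistent segment sums are rejected at construction", {
  expect_error(
    mir_gene_model("bad",
                   data.frame(kind = c("exon", "intron", "exon"),
                              length = c(100L, 50L, 100L)),
                   mirna_span = c(1, 21), gene_length = 300L),
    "validation error")
})

test_that("miRNA localization reproduces the printed segment annotations", {
  loc <- locate_feature(models$MIR160a, models$MIR160a$mirna_span)
  expect_equal(loc$kind, "intron"); expect_equal(loc$index, 2L)
  loc <- locate_feature(models$MIR5175a, models$MIR5175a$mirna_span)
  expect_equal(loc$kind, "intron"); expect_equal(loc$index, 10L)
  loc <- locate_feature(models$MIR1120b, models$MIR1120b$mirna_span)
  expect_equal(loc$kind, "intron"); expect_equal(loc$index, 1L)
  for (g in c("MIR166a", "MIR167h", "MIR530-5p", "MIR1432-5p")) {
    loc <- locate_feature(models[[g]], models[[g]]$mirna_span)
    expect_equal(loc$kind, "exon"); expect_equal(loc$index, 1L)
  }
})

test_that("MIR5203 miRNA is computed to lie in exon 10", {
  # the catalogue row prints no segment annotation for this span; the
  # coordinate map places it in the last exon
  loc <- locate_feature(models$MIR5203, models$MIR5203$mirna_span)
  expect_equal(loc$kind, "exon")
  expect_equal(loc$index, 10L)
})

test_that("junction-spanning features are reported, never assigned", {
  loc <- locate_feature(models$MIR160a, c(200, 210))  # exon1 ends at 206
  expect_equal(loc$kind, "junction-spanning")
  expect_true(is.na(loc$index))
  expect_error(locate_feature(models$MIR160a, c(1190, 1210)),
               "coordinate error")
})

test_that("mature sequence lengths match the printed 21/22-nt forms", {
  expect_equal(nchar(models$MIR166a$mirna_seq), 21L)
  expect_equal(nchar(models$MIR167h$mirna_seq), 22L)
  for (m in models) {
    expect_equal(nchar(m$mirna_seq),
                 m$mirna_span[2] - m$mirna_span[1] + 1L)
  }
})

test_that("splice isoform enumeration covers all 2^n retained subsets", {
  iso <- enumerate_splice_isoforms(models$MIR160a)
  expect_equal(nrow(iso), 8L)
  expect_equal(anyDuplicated(iso$retained_introns), 0L)
  expect_equal(iso$isoform_id[1], "A")
  # unspliced isoform: full length, hairpin retained
  expect_equal(iso$spliced_length[iso$retained_introns == "1,2,3"], 1198L)
  expect_true(iso$retains_mirna_hairpin[iso$retained_introns == "1,2,3"])
  # removing the miRNA-bearing intron 2 loses the hairpin
  expect_false(iso$retains_mirna_hairpin[iso$retained_introns == "1"])
  expect_false(iso$retains_mirna_hairpin[iso$retained_introns == "1,3"])
  expect_true(iso$retains_mirna_hairpin[iso$retained_introns == "1,2"])
  # spliced length equals full length minus the removed intron lengths
  intron_len <- c(73L, 211L, 214L)
  for (r in seq_len(nrow(iso))) {
    kept <- as.integer(strsplit(iso$retained_introns[r], ",")[[1]])
    expect_equal(iso$spliced_length[r],
                 1198L - sum(intron_len[setdiff(1:3, kept)]))
  }
  # strictly decreasing along any nested chain of removals
  agg <- tapply(iso$spliced_length, iso$n_retained, max)
  expect_true(all(diff(agg[order(as.integer(names(agg)))]) > 0))
})

test_that("intronless genes have exactly one full-length isoform", {
  iso <- enumerate_splice_isoforms(models$MIR166a)
  expect_equal(nrow(iso), 1L)
  expect_equal(iso$spliced_length, 1320L)
  expect_true(iso$retains_mirna_hairpin)
})

test_that("isoform enumeration refuses past the combinatorial cap", {
  segs <- interleave_segments(rep(10L, 14L), rep(5L, 13L))
  m <- mir_gene_model("many", segs, mirna_span = c(1, 5))
  expect_error(enumerate_splice_isoforms(m), "cap")
  expect_equal(nrow(enumerate_splice_isoforms(m, max_introns = 13L)),
               2L^13L)
})

test_that("validation report: structure passes 8/8, known star rows flag", {
  rep <- validate_models(models)
  bad <- rep[!rep$pass, ]
  expect_equal(sort(bad$gene_id), c("MIR160a", "MIR5175a"))
  expect_true(all(bad$check == "star_seq_length_matches_span"))
  non_star <- rep[rep$check != "star_seq_length_matches_span", ]
  expect_true(all(non_star$pass))
  expect_equal(nrow(validate_models(list())), 0L)
})

test_that("validation flags a sequence/span width mismatch", {
  m <- suppressWarnings(mir_gene_model(
    "w", data.frame(kind = "exon", length = 100L),
    mirna_span = c(10, 30), mirna_seq = strrep("A", 20)))
  rep <- validate_models(list(m))
  expect_false(rep$pass[rep$check == "mirna_seq_length_matches_span"])
})

test_that("gene models round-trip through the compact TSV", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_models_tsv(models, f)
  back <- suppressWarnings(read_models_tsv(f))
  expect_equal(length(back), length(models))
  for (k in seq_along(models)) {
    expect_equal(back[[k]]$segments, models[[k]]$segments)
    expect_equal(back[[k]]$mirna_span, models[[k]]$mirna_span)
    expect_equal(back[[k]]$mirna_seq, models[[k]]$mirna_seq)
  }
})

test_that("GFF3 export writes 1-based inclusive features", {
  f <- withr::local_tempfile(fileext = ".gff3")
  write_models_gff3(models["MIR160a"], f)
  gr <- rtracklayer::import(f)
  mir <- gr[gr$type == "miRNA"]
  expect_equal(GenomicRanges::start(mir), 344)
  expect_equal(GenomicRanges::end(mir), 364)
  expect_equal(sum(gr$type == "intron"), 3L)
})
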