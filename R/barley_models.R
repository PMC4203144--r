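# The eight barley MIR gene structures (GenBank KJ664928-KJ664935):
# printed gene lengths, exon/intron lengths in gene order, miRNA and
# miRNA* spans (1-based from the first gene nucleotide) and mature
# sequences. Built in code so the catalogue is usable without downloads.

#' Barley MIR gene model catalogue
#'
#' The eight published barley MIR gene structures (MIR160a, 166a, 167h,
#' 530-5p, 1432-5p, 1120b, 5175a, 5203) as [mir_gene_model()] objects:
#' exon/intron lengths, miRNA and miRNA* coordinates within the gene, and
#' mature sequences. miR160a lies in intron 2 of a 3-intron gene, miR5175a
#' in intron 10 of a 10-intron gene; 166a and 167h are intronless.
#'
#' @return named list of [mir_gene_model()] objects.
#' @export
barley_mir_models <- function() {
  mk <- function(id, len, ex, iv, mspan, sspan, mseq, sseq) {
    mir_gene_model(gene_id = id, segments = interleave_segments(ex, iv),
                   mirna_span = mspan, star_span = sspan,
                   mirna_seq = mseq, star_seq = sseq, gene_length = len)
  }
  models <- list(
    mk("MIR160a", 1198, c(206, 47, 99, 348), c(73, 211, 214),
       c(344, 364), c(415, 435),
       "UGCCUGGCUCCCUGUAUGCCA", "GCGUGCAGGAGCCAAGCAUG"),
    mk("MIR166a", 1320, 1320, integer(0),
       c(174, 194), c(94, 114),
       "UCGGACCAGGCUUCAUUCCCC", "GGAAUGUUGUCUGGUUCAAGG"),
    mk("MIR167h", 1293, 1293, integer(0),
       c(119, 140), c(175, 195),
       "UGAAGCUGCCAGCAUGAUCUGA", "AGGUCAUGCUGGAGUUUCAUC"),
    mk("MIR530-5p", 1408, c(201, 276), 931,
       c(72, 92), c(171, 192),
       "UGCAUUUGCACCUGCACCUAC", "UAGGUGCAGUGGCAUAUGCAAC"),
    mk("MIR1432-5p", 2083, c(448, 458, 304), c(739, 134),
       c(116, 136), c(188, 208),
       "UUCAGGAGAGAUGACACCGAC", "AGGUGUCAUCCCGCCUGAACA"),
    mk("MIR1120b", 2884, c(242, 35, 173), c(2034, 400),
       c(1250, 1273), c(1193, 1216),
       "CUUAUAUUAUGGAACGGAGGGAGU", "UCCCUCCGUCCCAUAAUAUAACAA"),
    mk("MIR5175a", 5935,
       c(857, 139, 52, 1511, 591, 147, 290, 112, 305, 201, 187),
       c(77, 78, 91, 229, 81, 90, 85, 88, 112, 612),
       c(5346, 5366), c(5293, 5312),
       "AAGAAUUUUGGGACGGAGGGA", "CCUUCGUCCCAAAAUUCUUGA"),
    mk("MIR5203", 6826,
       c(432, 105, 123, 60, 97, 74, 54, 84, 123, 477),
       c(950, 2190, 168, 602, 81, 485, 84, 533, 104),
       c(6546, 6566), c(6477, 6497),
       "ACUUAUUUUGGAACGGAGGGA", "ACUCUGCCCUAAAAUAAGUGU")
  )
  stats::setNames(models, vapply(models, `[[`, "", "gene_id"))
}
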