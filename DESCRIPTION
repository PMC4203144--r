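Package: mirheat
Title: Heat-Responsive Plant miRNA Analysis: MIR Gene Architecture,
    Target Duplex Scanning, Hairpin Folding, Degradome t-Plots and
    2^-dCt Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the computational side of heat-stress miRNA studies
    in barley and other plants. Represents MIR gene exon/intron architecture
    with miRNA/miRNA* coordinates and enumerates splice isoforms; scans
    transcripts for miRNA target sites under a mismatch-point scheme (G:U
    wobble 0.5, other substitutions 1, no indels) with seed-region and
    total-score discard rules; evaluates duplex hybridization free energy
    with a nearest-neighbor model and filters/ranks sites at an MFE
    threshold; folds pri-miRNA windows to minimum-free-energy hairpins and
    assesses miRNA/miRNA* duplex pairing; maps degradome tags to
    transcripts, builds t-plots against the transcript-mean baseline and
    categorizes cleavage-site support; and summarizes RT-qPCR replicates by
    2^-dCt relative quantification. A synthetic-data module generates
    transcripts with planted target sites, degradome tag pileups,
    hairpin-bearing MIR gene models and replicated Ct tables with known
    fold changes, so the whole pipeline is testable without raw plant
    material.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
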