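#!/usr/bin/env Rscript
# Fold the +/-120-nt window around the miRNA of the simulated precursor
# to its MFE hairpin and assess miRNA/miRNA* duplex pairing.

suppressPackageStartupMessages(library(mirheat))
sim_dir <- "results/simulated"
if (!file.exists(file.path(sim_dir, "precursor.fasta"))) {
  stop("run analysis/02_simulate.R first")
}

fa <- read_fasta(file.path(sim_dir, "precursor.fasta"))
gene <- read_models_tsv(file.path(sim_dir, "synth_gene.tsv"))[[1]]

st <- fold_precursor(fa$residues, gene$mirna_span, gene$star_span,
                     flank = 120)
message("Window ", nchar(st$window_seq), " nt (offset ",
        st$window_offset, "); MFE ", round(st$mfe, 2), " kcal/mol; ",
        nrow(st$pairs), " base pairs")
message("miRNA/miRNA* duplex paired fraction: ",
        round(st$duplex_paired_fraction, 3),
        " (designed duplex pairs 19/21 positions: 2-nt 3' overhangs)")

write_vienna(st, "results/hairpin.vienna", id = gene$gene_id)
write_tsv(data.frame(gene_id = gene$gene_id,
                     window_nt = nchar(st$window_seq),
                     mfe_kcal = st$mfe,
                     duplex_paired_fraction = st$duplex_paired_fraction),
          "results/hairpin_summary.tsv")
message("Wrote results/hairpin.vienna, results/hairpin_summary.tsv")
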