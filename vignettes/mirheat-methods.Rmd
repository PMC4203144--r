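---
title: "Methods: MIR gene architecture, target duplex scanning, hairpin folding, degradome t-plots and 2^-dCt quantification"
author: "mirheat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirheat)
```

# Scope

`mirheat` implements the computational side of a heat-stress miRNA study
in barley: the structural arithmetic of MIR genes and their splice
isoforms, prediction of miRNA target sites on mRNAs by exhaustive
ungapped scanning under a mismatch-point scheme, nearest-neighbor free
energies for the resulting duplexes, minimum-free-energy folding of
pri-miRNA hairpin windows, degradome (PARE) t-plot analysis of cleavage
sites, and 2^-dCt relative quantification of RT-qPCR data. A
synthetic-data module generates every input with known ground truth, so
the full pipeline is testable without plant material or downloads.

# MIR gene architecture and splice isoforms

A MIR gene is an ordered run of exon/intron segments; coordinates are
1-based inclusive and numbering starts at the first gene nucleotide.
`build_coordinate_map()` turns segment lengths into cumulative spans;
`locate_feature()` reports the unique segment fully containing a span.
A feature that crosses an exon/intron boundary is a first-class
`junction-spanning` outcome rather than an error, because splice-isoform
reasoning needs it: a junction-spanning hairpin cannot survive the
splicing of either flanking segment.

`enumerate_splice_isoforms()` enumerates all `2^n` retained-intron
subsets. Isoforms are lettered in decreasing retained-intron count
(A = unspliced), ties ordered by the retained set; an isoform retains
the miRNA hairpin iff the segment hosting the miRNA (and, when
annotated, the star strand) is an exon or a retained intron. The
enumeration refuses above a configurable cap (default 12 introns) as a
combinatorial guard.

The package ships the eight published barley MIR gene structures
(`barley_mir_models()`), built in code from the printed exon/intron
lengths, miRNA/miRNA* spans and mature sequences. Two star-strand
entries in the published table are internally inconsistent (the MIR160a
star span is 21 nt wide but its printed sequence is 20 nt; the MIR5175a
star span is 20 nt wide with a 21-nt sequence). The catalogue keeps the
printed values verbatim and `validate_models()` reports exactly these
two discrepancies; every other structural check passes for all eight
genes. The MIR5203 row prints no segment annotation for its miRNA span;
the coordinate map places it in exon 10, and the package reports the
computed segment rather than assuming one.

# Target site scanning

Site discovery is an exhaustive, deterministic scan: every window of
miRNA width on the transcript sense strand is scored against the miRNA
in antiparallel register (miRNA position `i`, counted from the sRNA 5'
end, pairs window position `L - i + 1`). Indels are not allowed, so the
duplex register is fixed. Per column:

* Watson-Crick pair — 0 points,
* G:U wobble — 0.5 points,
* any other substitution — 1 point.

A window is discarded when its total score reaches 4 points, or when
the substitution score over sRNA positions 1–12 exceeds 2.5 points. The
published rule sentence can be read with the two thresholds joint or
separate; the default (`discard_combination = "either"`) treats them as
independent discard rules — the stricter and more conventional reading
for plant targets — while `"both"` reproduces the literal conjunction.
Windows containing N are skipped and counted. The original study
intersected three external prediction tools and then applied these
rules; the scanner replaces that consensus because the stated scoring,
not the tools, is the reproducible content. Externally produced site
lists can still be intersected with the scan output by the caller.

Surviving windows are then filtered by hybridization energy: only
duplexes with MFE at or below −15 kcal/mol (inclusive) are kept, and
survivors are ranked by ascending MFE with ties broken by total score,
target id and coordinate. The threshold is a configuration value
(`scan_config()`): the study quoted MFEs from third-party predictors
with unknown parameter sets, so absolute agreement on real accessions
is not expected and the cutoff must be interpretable under the
package's own energy model.

# Nearest-neighbor energies

Duplex energies use a versioned parameter file
(`turner2004-simplified-v1`) of published nearest-neighbor RNA/RNA
dG37 constants: the 6×6 stack table over Watson-Crick and G:U wobble
pairs, loop-length initiation tables, affine multiloop terms, duplex
initiation (+4.10 kcal/mol) and a +0.50 kcal/mol terminal penalty per
duplex end closed by A:U or G:U. For the fixed ungapped register the
duplex energy is a plain sum: initiation + stacks over adjacent paired
columns (wobble pairs stack but count as weak ends) + a 1×1
internal-loop-style penalty (1.0 kcal/mol) per mismatch column. G:U
wobbles therefore both score 0.5 mismatch points in the scanner and
pair thermodynamically in the energy model, which is exactly how plant
target-validation practice treats them.

Simplifications relative to a full Turner model: no dangling ends, no
sequence-dependent loop terminal mismatches, no special 1×1/2×2 loop
tables, no loop-asymmetry term, and linear (0.1 kcal/mol per nt)
extrapolation of loop penalties past the 30-nt tables instead of a
logarithmic term. Parameters are a TSV under `inst/extdata/`; an
alternative file can be supplied to `load_energy_model()`. Temperature
is fixed at 37 °C parameters.

# Hairpin folding

`fold_precursor()` extracts a window of ±120 nt (the `flank` argument;
the study used "approximately 120") around the miRNA and folds it by a
simplified Zuker dynamic program over the same parameter file: stacks,
hairpin/bulge/internal loop initiation by length, affine multiloop
energy `a + b·branches + c·unpaired`, minimum hairpin loop 3 nt, no
pseudoknots, interior loops capped at 30 unpaired nt (which also bounds
runtime), window length capped at 1,000 nt (folding is O(n³)). The
traceback is deterministic, preferring 5'-most explanations among
co-optimal structures, so outputs are stable across runs.
`assess_mirna_star_duplex()` reports the fraction of miRNA positions
paired into the star span of the MFE structure.

Under `pair_max_model()` every admissible pair contributes −1 and all
loop terms vanish, so the DP objective reduces to Nussinov base-pair
maximization; the test suite uses an independent Nussinov
implementation (and, at small sizes, exhaustive enumeration of all
admissible structures) as oracles. The returned MFE always equals an
independent loop-decomposition rescoring of the returned pair set.

# Degradome t-plots and cleavage categories

Degradome tags (26–27-nt 5'-end signatures of uncapped, polyadenylated
fragments) map by exact match of their 5'-most 20 nt (`match_len`; the
3' portion of such tags is adapter-proximal and of variable quality)
against transcript sense strands. Multi-mapping tags count at every
locus and are flagged ("count-to-all"; a fractional policy is
available). Per-position 5'-end counts form the t-plot; the baseline is
the transcript-wide mean count, the quantity drawn as the dotted line
in published t-plots. No cross-library normalization is applied by
default because calls compare positions within one transcript.

The expected slicing position of an alignment is the target nucleotide
paired to miRNA position 10 (the 5' end of the downstream fragment),
`end − 9` in transcript coordinates. `call_cleavage()` takes the
maximum count within ±1 nt (`tolerance`) of that position and assigns
categories in the conventional degradome style, anchored to the
transcript-mean baseline: 0 = unique transcript-wide maximum above the
mean, 1 = tied maximum above the mean, 2 = above the mean, 3 = more
than one read but at or below the mean, 4 = otherwise. The source
study shows t-plots and the mean baseline but states no call rule;
this five-tier scheme makes that evidence computable. Calls are made
per surviving alignment, so transcripts without predicted sites yield
no calls at all.

# 2^-dCt quantification

dCt = Ct(target) − Ct(reference); the fold change is 2^-dCt. Summaries
are per (gene, timepoint): mean ± SD of the per-replicate fold changes
in each condition — SD on the fold-change scale, matching how such
bars are drawn — and the heat/control ratio of cell means as
`relative_to_control` (the control cell is the "1" standard), with
log10 of that ratio for display. Ratio-of-means is the default because
it follows directly from the stated 2^-dCt method; a ddCt variant
(2 to the power of the negated difference of mean dCts) is available
as `method = "ddct"`. Axis-shifting used in published charts is
presentation-only and excluded. The reference gene is a column, not a
hard-coded assumption.

# Synthetic data: what it emulates and what it does not

* `make_target_transcriptome()` — transcripts of i.i.d. uniform ACGU
  background carrying at most one planted site each, built by mutating
  the reverse complement of the miRNA to a requested mismatch/wobble
  composition; the background is rejection-sampled so no off-target
  window survives the discard rules. Uniform composition has no codon
  or UTR structure; it is sufficient for scanner and degradome testing
  and keeps rejection sampling cheap (a surviving window in random
  sequence is astronomically rare for 21-mers).
* `make_degradome_library()` — `signal_reads` tags at each planted
  site's expected cleavage position plus Poisson(background_rate) tags
  per position, sequences copied from the transcript; tags running past
  the 3' end are truncated and flagged. Poisson noise is the simplest
  exchangeable background against a transcript-mean baseline.
* `make_mir_gene()` — a designed hairpin (miRNA arm, loop, star arm =
  reverse complement of the first `stem_len − 2` miRNA nucleotides
  plus 2 unpaired nt, the 2-nt 3'-overhang duplex geometry) embedded
  in a chosen exon or intron of a random gene. The default high-GC arm
  makes the designed stem the unambiguous fold optimum, which is what
  a recovery test needs.
* `make_ct_table()` — control dCt ~ N(0, sd), heat dCt ~
  N(−log2(fold), sd): noise on the Ct (cycle) scale, as an instrument
  produces it, so fold noise is log-normal. Defaults follow the study
  conditions: 3 biological replicates and a 13-fold induction (the
  strongest published pri-miRNA response).

Every generator takes a mandatory seed and is a deterministic function
of (arguments, seed). Passing tests on these inputs demonstrates the
algorithms' correctness and parameter recovery under the stated noise
models; it does not demonstrate robustness to real-transcriptome
features (repeats, biased composition, partial degradation, multiple
sites per transcript).

# Numerical choices and edge cases

* Coordinates are 1-based inclusive internally and in GFF3; BED export
  converts to 0-based half-open at the I/O boundary only.
* All sequences are normalized to the RNA alphabet on input (T→U);
  records read with T are flagged `DNA-as-read`. N is tolerated but any
  scanning or folding window containing N is excluded, with a count.
* Energy comparisons in the folding traceback use an absolute epsilon
  of 1e-9 kcal/mol; co-optimal ties resolve 5'-most first.
* Ungapped duplex sums are exact up to floating-point summation order
  (deviations ~1e-14 against a reordered reference summation).
* A single replicate per condition is allowed with a warning (SD
  reported as 0); a missing matched control cell is an error naming
  the cell.
* Degradome category assignment needs no minimum read count beyond the
  tiers themselves; an all-zero t-plot is category 4 with 0 reads.

# Problem sizes used in the checks

The shipped verification suites use sizes chosen to exercise each
property well past its edge cases while staying desk-scale: 1,000
random miRNA/transcript pairs (transcripts ≤ 500 nt) for
scanner-vs-brute-force equivalence, 10,000 random duplexes for energy
additivity, 500 random sequences ≤ 200 nt for Nussinov equivalence
plus exhaustive-enumeration minimality at ≤ 26 nt, 100 seeded
degradome libraries on 1,000-nt transcripts, and 200 seeded Ct tables.
The standalone reproduction script (`scripts/acceptance.R`) recomputes
the same quantities at moderately smaller sizes (200 scanner pairs,
2,000 duplexes, 120 folds, 30 degradome seeds, 200 Ct seeds).

# Known limitations

* The energy model is deliberately simplified; absolute dG values for
  real precursors will differ from full Turner-model folders, and the
  −15 kcal/mol duplex threshold should be read under this model.
* With Ct noise SD 0.1 and 3 replicates, the log fold-change estimate
  has SD ≈ 0.1·ln2·√(2/3) ≈ 0.057, so about 92% (not more) of seeds
  recover a 13-fold induction within ±10% on the fold scale. The
  distributional unit test asserts this analytically expected
  behavior; a stricter 95%-of-seeds bound is not attainable under
  these noise settings and is reported as measured.
* Degradome mapping is exact-prefix only (no mismatches, no genome
  index); translational-repression site classes, site accessibility
  and cross-species conservation filtering are out of scope, as are
  protein-level filters requiring external databases.
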