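---
title: "Calling, quantifying and testing proximity-editing RNA localization signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling, quantifying and testing proximity-editing RNA localization signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlptools)
```

## The measurement model

A proximity-editing reporter couples an RNA deaminase (TadA-style, A-to-I
read as A>G; or APOBEC1-style, C-to-U read as C>T) to a compartment anchor
and a poly(A)-binding domain. RNAs that dwell near the anchored reporter
accumulate base conversions; RNAs that never visit the compartment do not.
Sequencing of induced cells against uninduced controls turns localization
into a counting problem on per-site base counts. Three properties of this
design shape every statistic in the package:

* editing integrates over hours, so signal is cumulative and 3'-biased —
  the poly(A)-binding domain tethers the enzyme near the transcript 3' end;
* each enzyme has a dinucleotide preference (AC for the C>T chemistry, TA
  for the A>G chemistry), visible in the sequence context of true sites;
* uninduced controls carry only sequencing/alignment noise, so "absent from
  controls" is a powerful specificity filter.

All internal coordinates are 0-based half-open; GTF input is converted on
read. Multi-isoform genes are collapsed to one designated transcript per
gene (the longest, configurable via `designate_transcripts()`), because all
per-gene positional quantities need a single frame of reference and the
choice of isoform is not identifiable from site counts alone.

## Event calling

`call_events()` emits an event at a site when, in order:

1. **control absence** — every control sample shows at most
   `control_max_alt` (default 0) reads of the chemistry's alt base there.
   Sites never covered by any control are rejected by default (an
   unverifiable site is not evidence); `missing_control = "keep"` relaxes
   this.
2. **single SNV type** — among non-reference reads, the chemistry's alt base
   carries at least `purity_min_fraction` (default 0.9) and no other alt
   base reaches `min_alt`. A literal "exactly one alt base observed" rule
   would be depth-dependent — deep sites always carry stray mismatches — so
   purity is expressed as a fraction plus an absolute cap.
3. **support** — at least `min_alt` (default 3) edited reads.
4. **per-transcript floor** — only transcripts with at least
   `min_events_per_transcript` (default 3) events, each with editing ratio
   above `min_event_ratio` (default 0.01), keep their events. We apply the
   ratio per event, not as a transcript aggregate; the per-event reading is
   the one that extends coherently to single cells, where the same 3-edit
   floor is applied per cell.

Strand is resolved before conversion classification, so a genomic T>C site
on a minus-strand transcript is an A>G event. Base-quality and
alignment-artifact filtering are assumed to have happened upstream of the
site-count table — they operate on alignments, which are outside this
package's inputs.

## Quantification

Per-gene edit occurrences $E_{g,s}$ count every edit on every read. The two
sample-level summaries deliberately differ in their numerator:

$$\mathrm{ECPM}_{g,s} = \frac{E_{g,s}}{\sum_i E_{i,s}} \times 10^6
\qquad
\mathrm{EPM}_s = \frac{\#\text{distinct sites}_s}{\#\text{mapped reads}_s}
\times 10^6$$

ECPM is a per-gene share of occurrences; EPM is whole-sample activity in
distinct sites. Neither normalizes by gene length: with a 3'-anchored
reporter, edit counts are empirically length-independent (the test suite
verifies Spearman $|\rho| < 0.1$ against transcript length on data generated
with length-free editing). Editing efficiency $E_{g,s}/\mathrm{reads}_{g,s}$
feeds the localization index

$$\mathrm{LI}_g = \log_2
\frac{\mathrm{efficiency}_{\mathrm{compartment},g}}
     {\mathrm{efficiency}_{\mathrm{cytoplasm},g}},$$

computed only for genes detected in both samples (zero-edit genes are
excluded and reported; an optional 0.5 pseudocount mode exists but is off by
default because a detection-gated LI is the cleaner estimand). Expression-
stratified summaries (`binned_expression_summary()`) use ten equal-width
bins on the log2 expression axis after dropping genes with linear expression
at or below 1, reporting mean ± SE (sample SD, $n-1$, over $\sqrt n$); bins
are left-closed with a closed top bin.

`metagene_polyA_density()` histograms each event's transcript-coordinate
distance upstream of the poly(A) site over a 1,000-nt window (50-nt bins,
normalized to unit mass; farther events are counted separately rather than
silently dropped).

## Temporal clustering

LI time courses are standardized row-wise (mean 0, SD 1, $n-1$ denominator;
constant rows are excluded — a flat gene has no shape to cluster) and
clustered by UPGMA on correlation distance $d = 1 - r$. Pearson correlation
is the default; the distance cares about trajectory shape, not level, which
is exactly what row z-scoring leaves behind. `stats::hclust(method =
"average")` provides the merging (its tie handling is deterministic), an
independent brute-force UPGMA implementation in the test suite confirms the
merge heights, and trees export as Newick. The flat-cluster count `k` is
user-chosen: the cluster structure of a time course is a claim the analyst
makes, not a parameter the algorithm can infer.

## Single-cell statistics

QC proceeds in the order the quantities become available: genes kept when
supported by ≥ 5 unique reads in ≥ 2 cells (when a read-support matrix is
provided); cells dropped below 9,000 detected genes (detected = TPM > 0,
the simplest faithful reading of "expressing"); then editing-activity
outliers removed — in NES (cytoplasmic) mode by Tukey fences at 1.5 IQR on
the chemistry-consistency ratio and on edited-gene counts, in ERM mode by a
hard 200-edited-gene floor plus a Q3 + 3 IQR ceiling. Quartiles use linear
interpolation (type 7); the fences move with the quantile convention, so
the convention is pinned and configurable. Fewer than four cells at the IQR
step is an error: quartiles of three points are not fences.

A gene's **detection rate** is the fraction of passing cells with ≥ 3 edits.
Rates bin into deciles `[0,0.1), ..., [0.9,1.0]`; zero-rate genes are
excluded from the histogram (and reported), keeping the observed support
comparable to the shuffled one.

The **expression-matched shuffle null** asks whether detection-rate
heterogeneity exceeds what transcript abundance alone explains: per cell,
the observed edit total is reassigned across genes by a multinomial draw
with probabilities proportional to that cell's TPM; genes reaching ≥ 3
simulated edits in ≥ 1 cell are retained; rates are binned as above. Three
independent shuffles (deterministic substreams of one seed) give per-bin
mean and SD. `chisq_gof()` rescales the expected histogram to the observed
total, merges bins with expected count < 5 into their right neighbor
(standard validity condition), and reports $\sum (O-E)^2/E$ with
$df = \text{bins} - 1$. With only three shuffles the expected counts carry
estimation noise that makes the test mildly anticonservative in theory; at
the scales exercised in the test suite (50 cells × 300 genes, 200 null
datasets) the measured size stays well below nominal-plus-noise bounds, and
`n_shuffles` is exposed for analysts who want tighter expected values.

## Detained introns

For intron $k$ of the designated transcript,

$$\mathrm{ratio} = \frac{\text{mean intron coverage}}
{(\text{mean exon}_k + \text{mean exon}_{k+1})/2},$$

undefined (flagged, excluded) when both flanks are silent. The ratio is
scale-invariant per cell, so per-cell depth normalization is moot; no
cross-cell depth correction is applied. Group comparisons use a two-sided
Mann-Whitney U from midranks. For small groups the p-value is the exact
permutation tail of $|U - n_1 n_2/2|$ — correct in the presence of ties,
where the textbook exact distribution is not — and the normal approximation
with tie and continuity corrections takes over when the enumeration exceeds
2×10⁵ assignments. The median fold change guards a zero median with a
recorded pseudocount (half the smallest positive ratio by default).

## Sequence context

`extract_context()` slices ±10 nt around each edited base, reverse-
complementing minus-strand events so every context reads 5'→3' in transcript
orientation; position 0 is the edited base and upstream positions are
negative, which makes the dinucleotide preferences read naturally (AC = A at
−1, edited C at 0). Events too close to a contig end are excluded and
reported. Frequency matrices have unit position sums; enrichment against a
user-supplied background composition (e.g. 3'-UTR base frequencies; uniform
by default — no genome-derived table is bundled) is log2.

## The simulators and what they do (not) show

Generators draw from named substreams of one master seed
(`substream_seed()`), so outputs are byte-identical per seed and adding a
generator never perturbs another. Default scales keep every end-to-end test
in seconds: 300 genes, 100 cells, 7 timepoints, 50 cells per phase.

* `make_transcriptome()`: 1–5 exons per gene (200–800 nt exons, 100–500 nt
  introns), both strands, with the chemistry's dinucleotide planted at a
  controlled exon density (default 5% of positions).
* `simulate_bulk()`: per-gene reads Poisson around expression (mean 100 per
  average gene); sites drawn per the positional law — 95% of mass uniform on
  50–250 nt upstream of the poly(A) site, the rest spread over the 1,000-nt
  window — at motif-consistent positions (90% fidelity); per-read editing
  probability 0.2 for compartment-enriched genes and 0.05 for background
  genes (a 4-fold contrast, i.e. a planted LI of 2); controls carry a 10⁻³
  per-read error. Each site's hot/cold stratum is drawn first and the
  position then sampled uniformly within the stratum, which preserves the
  law even when a gene's hot window holds few motif positions.
* `simulate_cells()`: gene-mean expression lognormal with sdlog 1.5 (a log2
  SD near 2.2, typical of detected-gene TPM spread), per-cell lognormal
  noise (sd 0.3), rows renormalized to TPM. Each cell's edit total is
  Poisson with mean 3.33 per gene — chosen so roughly half of genes carry
  the 3-edit detection floor in a given cell, matching the regime where
  about 5,000 of 10,000+ detected genes per cell are edited. Null genes
  receive a TPM-proportional multinomial (exactly the shuffle null's
  generating process); core/rare genes instead receive Poisson edits with
  mean `planted_mult × N_c / n_genes` (default multiplier 2.5, mean ≈ 8)
  only inside a random member-cell subset (95% / 5% of cells).
* `simulate_timecourse()`: rising (linear), peaked (unimodal, max at the
  middle timepoint) and flat classes with Gaussian noise (SD 0.3).
* `simulate_intron_coverage()`: lognormal flank coverage, intron coverage =
  flank mean × per-phase retention (defaults 0.5 in S vs 0.05 in G2/M, a
  10-fold detained-intron contrast) × lognormal noise.

The simulators emulate the *statistical structure* the analyses assume —
compartment-specific rates, 3' positional bias, motif preference, control
noise, subset-restricted single-cell editing, phase-dependent retention.
They do not emulate alignment artifacts, PCR duplication, SNP
contamination, overlapping genes, isoform switching, or sequencing-error
structure beyond a flat per-read rate. A passing suite therefore shows the
statistics are implemented correctly and recover planted truth under the
stated model, not that the model captures every failure mode of real
libraries — on real data the upstream alignment filters and control design
carry that weight.

## Numerical choices and degenerate inputs

* Quantiles: type 7 everywhere (documented because QC fences depend on it).
* SE: sample SD with $n-1$ over $\sqrt n$; single-member bins report SE 0.
* Bins: left-closed, top bin closed, across metagene, expression and rate
  histograms.
* Zero handling: zero-depth sites are skipped; zero-edit genes are excluded
  from LI with a reason; zero-rate genes leave the rate histogram but are
  reported; a zero-TPM cell is an error naming the cell.
* Determinism: UPGMA ties resolve deterministically; all generators are
  seed-reproducible byte for byte.

## Known limitations

Site-to-gene assignment uses the designated transcript per gene and assumes
genes do not overlap on a contig; overlapping loci would need an assignment
policy that site counts alone cannot arbitrate. The caller does not model
allele-specific expression or germline SNPs (handled in practice by the
control-absence filter and upstream masking). The chi-square test treats
shuffle means as known expectations; with the default three shuffles this
is mildly anticonservative, measurably so only far from the deeply
significant regimes the test is meant to flag.
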