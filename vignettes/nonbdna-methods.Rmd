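---
title: "Methods: non-B DNA motif detection, matched variant nulls, and MPRA analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-B DNA motif detection, matched variant nulls, and MPRA analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nonbdna)
```

This vignette is the package's own account of its methods: the motif
definitions and their parameters, the statistical models, the numerical
choices, what the synthetic-data generators do and do not emulate, and the
known limitations. All coordinates in the package are 0-based half-open on
the forward genomic axis; minus-strand features carry forward-axis
coordinates with a strand flag. VCF positions are converted from 1-based on
read, and BED is read and written as-is.

## Motif definitions and scanner semantics

All thresholds live in `scan_config()`. The defaults are the classical
definitions used in the non-B DNA literature; each is configurable.

| parameter | default | meaning |
|---|---|---|
| `g_run_min` | 3 | minimum G-run length for G4 |
| `g4_loop_min`, `g4_loop_max` | 1, 7 | G4 loop length bounds (nt) |
| `g4_min_runs` | 4 | minimum number of G-runs |
| `z_min_len` | 10 | minimum alternating purine/pyrimidine tract (bp) |
| `rep_arm_len` | 10 | IR/MR/DR arm length (bp) |
| `rep_max_spacer` | 4 | IR/MR/DR maximum spacer (bp) |
| `str_unit_min`, `str_unit_max` | 1, 6 | STR unit length bounds (bp) |
| `str_min_total`, `str_min_copies` | 10, 3 | STR array thresholds |
| `dr_str_purity` | 0.80 | DR arm STR-coverage suppression threshold |
| `h_ag_min_frac` | 0.90 | H-DNA A/G (or T/C) fraction, exclusive |
| `h_min_arm`, `h_max_spacer` | 10, 7 | H-DNA arm and spacer bounds |

**G-quadruplexes.** `scan_g4()` reports the leftmost-longest,
non-overlapping matches of the consensus pattern
`([gG]{3,}\w{1,7}){3,}[gG]{3,}`. A greedy regex engine finds the leftmost
start; the span is then extended to the longest end that still matches the
anchored pattern, because greedy backtracking can in principle settle on a
shorter span when a loop absorbs G bases (in practice the two agree on
essentially all inputs, which the test suite verifies against two
independent regex engines). Substructure is the maximal-G-run decomposition
of the span. Because the consensus loops may absorb G-runs shorter than
`g_run_min`, the decomposition can contain short runs; the hit validator
therefore checks the structural invariants on the *qualifying* runs (those
of length at least `g_run_min`): at least `g4_min_runs` of them, gaps
between consecutive qualifying runs within the loop bounds, and the span
terminating in qualifying runs at both ends. Minus-strand motifs are found
by scanning the reverse complement and mapping spans back to the forward
axis.

**Z-DNA.** Maximal runs in which adjacent bases strictly alternate between
purine (A/G) and pyrimidine (C/T) classes, length at least `z_min_len`.
The definition is strand-symmetric, so hits are emitted once, on "+".

**Inverted, mirror and direct repeats.** Exhaustive mode enumerates every
(start, spacer) placement of two `rep_arm_len` arms with
spacer `0..rep_max_spacer` where arm2 is the reverse complement (IR),
reverse (MR), or copy (DR) of arm1. The exhaustive set is what the
brute-force oracle in the tests reproduces; merged mode unions overlapping
same-class footprints and is what presence flags and densities use.
Optional arm extension (`extend_arms = TRUE`) grows arms maximally while
symmetry holds and is used when arm length itself is the quantity of
interest (perturbation validation). A DR candidate is suppressed when its
arm is at least `dr_str_purity` covered by a perfect tandem repeat (at
least two copies) of any unit up to half the arm length — such arms are STR
territory, keeping the two classes disjoint.

**STRs.** Maximal perfect tandem arrays with unit 1–6 bp, at least 3
copies and at least 10 bp total, allowing a trailing partial copy (copies
are counted as complete units). The reported unit is the lexicographically
smallest rotation, and arrays whose minimal period is shorter than the
nominal unit are suppressed so a dinucleotide array is not re-reported at
unit lengths 4 and 6.

**H-DNA.** Mirror repeats with arm at least `h_min_arm` and spacer at most
`h_max_spacer` whose footprint has `max(AG, TC)` fraction strictly above
`h_ag_min_frac`. Using the maximum of the two composition fractions lets
either strand be the purine-rich one.

**N policy.** N bases never participate in any motif: they break Z tracts
and STR periodicity, exclude repeat footprints, and are excluded (with
their contexts) from trinucleotide matching. The consensus G4 pattern's
`\w` loop class technically admits N; G-runs never do.

**Orientation.** `assign_orientation()` labels a stranded motif
non-template when its strand equals that of an overlapping gene (the
mRNA-like strand) and template otherwise; a motif overlapping several
genes yields one labeled record per gene, and a motif in no gene is
intergenic.

## Matched variant nulls and enrichment

`simulate_snp_controls()` draws, per replicate, one position uniformly
among all positions within 10 kb of the source SNP whose trinucleotide
(5' base, center, 3' base) is identical to the source's, restricted to the
callable mask and excluding the source position itself; sources with no
eligible position are dropped and counted. `simulate_indel_controls()`
preserves exact indel length and type and requires local GC — computed over
100 bp on each side of the indel footprint, both flanks pooled, truncated
at sequence ends, sites with an empty flank ineligible — within 0.025
(absolute) of the source's. `simulate_sv_breakpoints()` treats breakpoints
as points with the same GC matching and carries the SV class label through.
Replicates are independent uniform draws (the default is 10), and every
simulator is a pure function of its seed: identical inputs and seed give
byte-identical output.

`overlap_enrichment()` computes the observed fraction of variants whose
footprint (deletion: the deleted span; insertion/SNP: one anchor base;
breakpoint: a point) overlaps a merged motif set, the per-replicate
simulated fractions, and their ratio as the fold. The default test is a
two-sided Mann–Whitney U on per-variant distances to the nearest motif,
observed versus pooled simulated — distances carry more information than
the binary overlap, and the replicate-fraction comparison is available as
`test = "fraction"`. The CI is a percentile bootstrap over variants.

Two properties of this design worth knowing. First, the fold is a ratio of
overlap fractions with a fixed total variant count, so with motif bp share
m and true per-bp rate ratio f the estimator converges to f/(f·m + 1 − m),
i.e. it is slightly conservative for large f unless m is small; at the bp
shares used in the tests (≈ 0.6–1.6%) the deflation is 1–5%. Second,
context matching is itself a composition control: when motif sequence
composition differs from the background, matched controls redistribute
toward composition-similar regions — including other motifs — making the
null conservative for composition-driven signal. That is the desired
behavior (composition is a confounder), but it means planted positional
enrichments are recovered most cleanly when planted motifs are
composition-neutral, which is how the validation genomes are built.

## Positional and compartment profiles

`tss_metaprofile()` counts feature midpoints (bp coverage optional) into
strand-oriented offset bins around each TSS, negative offsets upstream in
transcription direction. Fold is density over the mean density of the
outermost 20% of bins; when that background is empty the overall mean
density is used instead, with a warning (otherwise a profile whose features
all sit in one bin would have an undefined fold). Midpoint counting avoids
the length-induced smearing of coverage mode.

`compartment_enrichment()` derives six genic compartments from the gene
models — 1 kb upstream of the TSS, 5'UTR, coding exons, 3'UTR, introns,
1 kb downstream of the TES — and assigns each bp once, with precedence in
that order (the paperless convention fixed here; overlapping annotations
must resolve somehow and promoter-proximal categories take priority). Fold
is the feature share over the compartment's genome share; the p-value is
the exact binomial tail, made two-sided by doubling the smaller tail and
capping at 1, then Bonferroni-adjusted within the call.

`promoter_proximal_ratio()` compares per-bp feature densities in
[−250, 0) versus [−1000, 0) upstream windows, pooled over genes (per-gene
densities vary too wildly at realistic feature counts), with a bootstrap
over genes for the SD. `eqtl_density_profile()` is the motif-centered
analog: eQTL points are binned by distance to the nearest motif footprint
(bin 0 = inside), densities are normalized by the exact number of genome
positions at each distance (computed by interval expansion, clipped to
chromosome sizes when given), and the background is the far 20% of
distance bins — bin 0 is the signal bin and never part of the background.

`orientation_bias_test()` corrects the observed non-template/template count
ratio among peak-overlapping genic G4s (k/m) by the background orientation
odds π/(1−π), where π is the non-template share among *all* genic G4
motifs; the p-value is the exact two-sided binomial test of k in k+m
trials at probability π, and the CI transforms the exact binomial CI of
k/(k+m) to the fold scale.

## MPRA activity and motif effects

`compute_activity()` applies the minimum-count filter (default 3) to both
channels independently — the filter's channel scope is a convention fixed
here — then sums surviving barcode counts per insert and replicate, scales
each channel to counts-per-million within its replicate, and forms
`log2((RNA_cpm + 1)/(DNA_cpm + 1))`; per-insert activity is the mean over
replicates. Summing before forming one ratio is robust to shallow
barcodes; the +1 pseudocount keeps zero-RNA inserts finite. Base-2 logs
throughout.

`gc_correct()` is ordinary least squares of activity on GC fraction;
corrected activity is the residual. With `drop_outliers = TRUE`, records
with |standardized residual| > 2.5 are removed and the model refit once;
both fits are reported and corrected activities come from the final fit
evaluated for every record. `zscore_by_gene()` standardizes within genes
with the sample SD, dropping (with a warning) genes with fewer than two
records or zero SD.

`motif_contrast()` compares with-motif versus without-motif records on the
raw, GC-corrected or z score, reporting the median difference with a
bootstrap SD, a two-sided Mann–Whitney U or Welch t p-value, and a
Bonferroni adjustment over the classes tested in the same call (Welch
because equal variances have no justification here). The
orientation contrast (template minus non-template among G4-containing
records), the Kruskal–Wallis trend over Z-DNA length bins (tie-corrected
H), the G-run-count association (group means with bootstrap CIs plus a
Jonckheere–Terpstra monotone-trend test, normal approximation), and the
joint motif/TFBS ranking (one Bonferroni family across all features)
complete the chain.

`pwm_scan()` scores every position and strand with base-2 log-odds of the
PFM against a background base distribution and converts scores to p-values
by exact dynamic programming over the integer-rescaled score distribution
under the background. Scores are rounded to multiples of 10⁻³ before the
DP; the induced p-value error is bounded by the probability mass within
one granule of the threshold score, and the test suite checks the DP
against brute-force enumeration of all words. PFMs read from JASPAR or
MEME text get +0.25 per cell before normalization (the JASPAR convention;
set `pseudocount = 0` to keep probability matrices untouched); zero cells
of un-pseudocounted matrices are floored at 10⁻¹⁰ during scanning.

## Perturbation library design

Disruptions: `disrupt_g4()` substitutes 1–3 G→T per targeted run (T can
neither seed a G-run nor restore one), re-drawing until no G4 remains when
every run is targeted; `scramble_zdna()` permutes the tract (exact multiset
preserved) until no Z hit overlaps the window;
`purine_to_pyrimidine_disrupt()` applies the A→C, G→T transversion map at
uniformly chosen purines and reports the residual alternating tract.

Introductions: `introduce_motif()` builds a motif to exact parameters,
replaces a same-length window, and rescans to confirm the intended hit with
the intended substructure and no motif of another class inside the window,
re-drawing random components up to a retry cap. Exact-footprint round
trips are impossible when the flank would extend the motif — a base
continuing a terminal run or a Z alternation, or a whole flanking G-run
within loop range that would chain into the consensus match — so the
editor also repairs the offending flank bases in a quarantine region of
`g4_loop_max + g_run_min` bp, using randomized non-run replacement bases
so retries explore different repairs (and can avoid creating restriction
sites).

`build_library()` assembles 15 + 200 + 15 = 230-mer oligos from a
perturbation grid plus one unedited oligo per insert, deduplicates
identical sequences with a cross-reference log, re-validates every oligo by
rescanning, and rejects edits that create SbfI (CCTGCAGG) or AgeI (ACCGGT)
sites, since those enzymes linearize the reporter vector; inserts whose
*unedited* sequence already contains a site cannot be repaired without
changing the original and are rejected up front with an error.

## Synthetic data: what it emulates, and what it does not

`gen_genome()` draws iid bases at a target GC and plants motifs at exact
coordinates through the introduction machinery; `gen_variants()` and
`gen_eqtls()` place events so the in-motif per-bp rate is a chosen multiple
of background (the in-motif count is the rounded expectation, which removes
needless binomial noise from recovery checks); `gen_gene_models()` tiles
non-overlapping genes with random strands; `gen_peaks()` covers genic G4s
with orientation-dependent probabilities so the background-corrected fold
is a chosen target; `gen_mpra_counts()` draws negative-binomial barcode
counts (overdispersion is standard for MPRA counts) around a true activity
that is gene baseline + GC slope × GC + motif effects + Gaussian noise,
with a fraction of shallow barcodes to exercise the count filter. Every
generator is a pure function of (configuration, seed).

The background sequence model is iid — no isochores, no repeat families,
no dinucleotide structure, no empirical mutational signatures. Passing
tests therefore demonstrate algorithmic correctness and statistical
calibration under the stated generative model, not performance on real
genomes, where motif density, composition heterogeneity and variant
clustering are all stronger.

## Problem sizes and numerical choices

The test suite validates each scanner against independent brute-force
enumeration on 1,000 random 200 bp sequences per class (and the G4 scanner
against two regex engines on 10,000 sequences); audits 10,000 simulated
controls per variant type for 100% constraint satisfaction; measures the
enrichment test's type-I error over 200 null datasets of 2,000 variants on
a 150 kb genome; recovers planted folds 2 and 5 from 10,000 breakpoints on
a 1 Mb genome with 250 planted composition-neutral repeats; recovers a
planted GC slope of 1.5 and seven motif effects from 5,000 synthetic
inserts; checks CI coverage of a planted 1.7 orientation fold over 100
peak draws on 5,000 genic G4s; and round-trips a 500-oligo perturbation
library. The acceptance script reruns the same pipeline at comparable
sizes from a user-supplied seed.

Numerical conventions: sample standard deviations throughout; z-scores of
constant vectors are zero with a warning; Mann–Whitney tests use the exact
null for small tie-free samples and the tie-corrected normal approximation
otherwise; binomial two-sidedness is by tail doubling capped at 1;
nearest-distance ties break toward the 5'-most subject, and signed
distances are negative when the query lies 5' of its nearest subject;
folds against an all-zero simulated overlap are reported as `Inf` with a
warning rather than an error.

## Limitations

The scanners implement sequence-level motif definitions, not structure
prediction: no thermodynamic G4 scoring, no imperfect or mismatched
repeats, no RNA G4s. The MPRA chain starts from barcode count tables —
read alignment, UMI deduplication and barcode-insert association are
upstream concerns — and combines replicates by averaging rather than joint
generative modeling. Genome-scale population datasets (gnomAD, GTEx,
ENCODE) are interfaces here, not bundled data: the package provides the
computations and readers, and validates them on synthetic data with known
truth.
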