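---
title: "Methods: models, parameters and design choices in phosmat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in phosmat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosmat)
```

`phosmat` analyses multiplexed (TMT) quantitative phosphoproteomics of
sperm maturing along the mouse epididymis. This vignette is the
package's own account of the statistical machinery: what each stage
assumes, which parameters matter, what the synthetic-data generator
does and does not emulate, and where the design was genuinely open.

## The quantification model

One TMT experiment yields a sites × channels matrix of reporter-ion
intensities, with channels mapped to (group, replicate) pairs by a
study design table — channel order is always taken from the design,
never from file column order. Reporter intensities are treated as
positive, multiplicatively noisy quantities: all inference downstream
works on ratios, which is why missing values are kept as `NA`, never 0
(a zero would silently become a denominator).

**Class-I filtering.** A phosphosite's localization probability is the
search engine's confidence that the phosphate sits on the reported
residue rather than a neighbour. Sites with probability ≥ 0.75 are
retained. The boundary is inclusive here, matching the standard class-I
definition; whether a site at exactly 0.75 should pass is genuinely
ambiguous in common usage, so both the threshold and its strictness
(`inclusive = FALSE`) are exposed.

**Normalization.** Each site row and each protein row is divided by the
mean of its non-missing values, so complete rows have mean exactly 1
across channels. Row means use non-missing values only; rows with no
positive non-missing value are dropped with a warning rather than
imputed — no imputation is attempted anywhere in the pipeline.
Normalization is idempotent on complete rows (tested to 1e-12).

**Protein calibration.** To keep protein-abundance changes from
masquerading as phosphorylation changes, each normalized site value is
divided by the normalized value of its parent protein at the same
channel. Two deliberately different failure modes:

* parent protein **absent** from the protein table → the normalized
  site values are used directly and the site is flagged
  (`protein_quantified = FALSE`);
* parent protein present but the channel value **missing or ≤ 0** →
  the calibrated value is missing. The fallback is reserved for
  proteins that could not be quantified at all; patching individual
  channels with unnormalized values would mix scales within a row.

With a constant protein row the calibration is the identity, and with
protein rows equal to the site rows it cancels exactly — both are
structural invariants in the test suite.

## Differential phosphorylation

Per site, an independent two-sided Student's *t* test with pooled
variance compares two groups. The test runs on log2-transformed
calibrated values by default: ratio-scale data is closer to log-normal
than normal, and the log scale treats up- and down-regulation
symmetrically. Since the transform used by comparable workflows is not
always stated, `log_scale = FALSE` reproduces a raw-scale test.

Degenerate inputs follow explicit contracts rather than erroring
mid-pipeline: two zero-variance groups with equal means give t = 0,
p = 1; zero pooled variance with unequal means gives p = 0 with a
signed-infinity t statistic; sites with fewer than two usable values in
either group are reported `ns` with a reason code.

The fold change is the ratio of group means on the linear scale
(comparison over reference), matching the common MaxQuant/Perseus
convention rather than a geometric mean. A site is `up` when p < α and
FC ≥ *f*, `down` when p < α and FC ≤ 1/*f*; defaults α = 0.05,
*f* = 1.5, both inclusive at the boundary. Benjamini–Hochberg q-values
are reported as an extra column but do not enter the direction call —
site-level significance here is deliberately on the raw p-value, as is
conventional for this assay's site-level screens. Swapping the group
labels maps FC to 1/FC, leaves p unchanged, and swaps the up/down
counts exactly (tested).

Site calls aggregate to proteins (`up-only`, `down-only`, `both`,
`none`); proteins in `both` carry sites regulated in opposite
directions, a signature of position-specific regulation. The
`overlap_with_proteome()` cross-tabulation quantifies how far
phosphorylation regulation is independent of abundance changes.

The inhibitor comparison (`run_inhibitor_comparison()`) intersects the
maturation-upregulated set with the inhibitor-downregulated set using
p < α **only**, without the fold-change filter: inhibitor-response site
sets are conventionally defined by significance alone, and the two set
definitions (p-only vs FC-filtered) are kept distinct throughout the
outputs.

## Kinase–substrate inference

Kinases recognise sequence motifs around their substrate sites, so a
site's ±7 flanking window (15-mer, `_`-padded at protein termini, the
site residue at position 8) carries kinase information.

**Scoring.** The similarity of two windows is the sum over the 15
aligned positions of their substitution-matrix score; any position
involving the padding character contributes 0. A site's score for a
kinase is the arithmetic mean of its similarity to each of the kinase's
reference substrate windows. This is a motif-similarity scheme in the
GPS family; within that family the matrix, the aggregation rule (mean
vs max) and the threshold level differ between versions, so all three
are this package's own choices, each exposed: BLOSUM62 (the Biostrings
copy by default, or any NCBI-format text matrix via
`read_substitution_matrix()`), mean aggregation, and an
FPR-calibrated cutoff. Negative substitution scores are kept — flooring
at zero discards discrimination between dissimilar residues.

**Cutoff calibration.** For each kinase the score cutoff is the lowest
value such that at most a fraction `fpr` (default 0.02) of background
windows score at or above it; ties resolve upward, and an `fpr` below
1/n yields a cutoff above every background score. The background
defaults to the experiment's own windows with flanking residues
shuffled around a fixed center (seeded), which matches the experiment's
amino-acid composition without external data. The held-out background
FPR is verified within binomial tolerance in the tests.

**Enrichment.** Substrate prediction is gated by residue class (S/T
kinases never claim pY sites, and vice versa). For each kinase and each
regulated set (up and down are two separate analyses sharing the
universe of all tested class-I sites), a 2×2 table — regulated vs
remainder × predicted substrate vs not — is tested with a one-sided
Fisher's exact test via the hypergeometric upper tail. One-sided
because the question is enrichment; a two-sided test would also flag
substrate depletion. The family rollup counts significantly enriched
kinases per family in each direction.

## Over-representation analysis

`ora_test()` is a generic hypergeometric ORA against user-supplied GMT
sets: p = P(X ≥ k) for X ~ Hypergeom(N, K, n), with set members
intersected with the background before counting and K = 0 sets
omitted. Annotation is protein-level — a site's hit contributes its
parent protein once. The background defaults to the proteins carrying
tested class-I sites: the only background constructible without
external annotation, and the standard choice for expression-derived hit
lists. The multiple-testing procedure is fixed to Benjamini–Hochberg,
the default of the enrichment tools this reconstructs.

## The synthetic-data generator

`generate_experiment()` emulates the structure of the real experiment
at the site-quantification level: 3 groups × 5 replicates (15
channels), sites on a protein panel, an S/T/Y residue mix defaulting to
89.1 / 10.24 / 0.66 % (the class-I composition observed in maturing
mouse sperm), localization probabilities with a low-confidence tail,
and a configurable fraction of sites (default 0.2) whose parent protein
is absent from the protein table, exercising the calibration fallback.

Intensities follow the multiplicative error structure TMT ratios
assume: `value = base × group_effect × 2^N(0, noise_sd_log2)` with
log-normal base abundances. Planted differential sites carry a
noiseless group-mean log2 difference of exactly `effect_log2fc` between
the last and first group; the middle group receives half the effect, so
corpus sits between caput and cauda as an intermediate phenotype and
the PCA/correlation QC shows the expected ordering. Planted kinase
activities assign motif-consistent windows (via `generate_windows()`)
to a share of the matching-direction differential sites, and the
emitted kinase reference contains both planted kinases and inactive
decoys.

Deliberate generator choices:

* **Planted sites always get localization probability > 0.9**; the
  low-localization mass (default 15%) falls on null sites only, so
  ground-truth recovery is measured on the class-I testable fraction
  rather than confounded with the filter.
* **Protein intensities are independent of site effects by default**,
  reflecting phosphorylation regulation being largely independent of
  abundance in this system; `couple_protein_effect = TRUE` instead
  gives parent proteins the same group effect as their planted sites,
  which the calibration step must cancel — a direct test of its
  purpose.
* **`noise_sd_log2` defaults to 0.25.** The replicate noise of the real
  ratios is not stated anywhere usable, so this is a free parameter set
  once to a magnitude typical of TMT ratio data; the null-calibration
  test does not depend on its value (the t-test is exact under
  log-normal noise at any σ).
* Windows use `_` padding beyond protein termini, matching the
  MaxQuant sequence-window convention; positions are 1-based.

What the generator does **not** emulate: spectra, co-isolation
interference, isotopic impurity, peptide-to-site rollup, missingness
mechanisms correlated with abundance, and correlated sites within a
protein. Passing recovery tests therefore demonstrate the correctness
and calibration of the statistical chain under its stated error model,
not robustness to the full pathology of real MS data.

## Numerical choices and problem sizes

* The one-sided Fisher p and the ORA p are computed via `phyper`; the
  test suite checks them against an exhaustive combinatorial-sum oracle
  (binomial coefficients built from explicit factor products, tails by
  the odds recurrence) over every table with N ≤ 60, at 1e-10.
* The pooled t-test is checked against numeric integration of the
  explicit t density (200 random small-sample cases, 1e-8).
* Cutoff calibration uses an empirical quantile with upward tie
  resolution, so the background guarantee is one-sided by construction.
* Test and acceptance problem sizes were chosen to give tight binomial
  tolerances while keeping the suite quick: 4000 sites for the null
  type-I check (±3 binomial SDs ≈ ±0.011), 2000 sites for planted-site
  recovery, 1000 + 1000 train/held-out background windows for FPR
  verification, and 20 seeded replicates of 500 sites for the
  planted-kinase ranking rate.

## Known limitations

* No moderated (limma-style) variance shrinkage: with n = 5 per group
  the pooled t-test is the stated method, but it is less powerful than
  empirical-Bayes alternatives at low n.
* No paired designs, no >2-group omnibus tests; the contrasts are
  two-group only.
* Kinase inference is motif-only: no protein–protein interaction
  context, no kinase-activity z-scores; closely related basophilic
  kinases are expected to co-enrich, which is why results carry the
  family rollup.
* Single-plex: no batch correction across TMT plexes and no reporter
  isotope-impurity correction.
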