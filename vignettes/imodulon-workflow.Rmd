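---
title: "Reconstructing a bacterial TRN with iModulons: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing a bacterial TRN with iModulons: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imodulome)
```

## The model

An RNA-seq expression compendium is a genes x samples matrix `X` of logTPM
values. The package decomposes it as

    X ~ M A

where the columns of `M` (genes x k) are statistically independent
gene-weight vectors and the rows of `A` (k x samples) are the corresponding
activities per sample. Because transcriptional regulation is sparse — a
regulator touches a small fraction of the genome — independent components
of expression data tend to be sparse gene vectors, and thresholding a
column of `M` yields an *iModulon*: an independently modulated gene set
that frequently coincides with a regulon. The activity row then tracks how
strongly that gene set is engaged in each sample, which is the quantity a
biologist compares across conditions.

The pipeline runs: compendium QC, robust ICA with data-driven
dimensionality, iModulon extraction, regulon enrichment against a draft
TRN, differential activity, and a sequence-level arm (operon clustering,
PSSM motif scanning, and a regulon-membership classifier).

## Compendium quality control

Three operations, applied in the fixed order *exclude, then
correlation-filter, then center* (the order is a package decision; the
operations commute only partially):

1. `exclude_failing_samples()` drops samples with fewer than 500,000 reads
   mapped to coding sequences, samples failing the upstream FASTQC screen,
   samples without usable metadata, and finally samples left without a
   replicate partner.
2. `replicate_correlation_filter()` computes all pairwise Pearson
   correlations within each (project, condition) replicate group. If *any*
   pair falls below the threshold (default 0.80; the sweep
   0.80/0.85/0.90/0.95 is available via `qc_threshold_sweep()`), the whole
   group is replaced by its unweighted arithmetic mean. "Any pair below"
   is the strictest reading of group inconsistency; it makes the count of
   averaged groups monotone in the threshold, which the test suite
   asserts.
3. `center_to_reference()` subtracts, per project, the mean profile of the
   project's reference condition, so activities are interpretable as
   deviations from a designated baseline. Centering is idempotent.

Hierarchical-clustering outlier screening (`sample_outlier_report()`) is
advisory only: it reports singleton samples under an average-linkage cut
on correlation distance but never excludes anything automatically, because
no principled cut height exists without inspecting the data.

## Robust ICA

`run_ica()` implements the fixed-point (FastICA-type) algorithm directly:

* **Whitening.** The top-`d` left singular vectors of `X` define the
  search subspace, scaled to unit variance. `X` is used as supplied — the
  reference centering is the centering step; no additional per-column
  centering is applied, so the reported `M %*% A` reconstructs `X` itself
  up to the discarded singular subspace.
* **Contrast.** log-cosh, symmetric (all components simultaneously),
  with symmetric decorrelation after each update; convergence tolerance
  1e-6, at most 1000 iterations.
* **Restarts and robustness.** The iteration is repeated from
  `n_restarts` random orthogonal initializations (default 10 in the
  package, 100 being a sensible production setting). All components are
  pooled and clustered with a density-based scan on the distance
  `1 - |Pearson r|` between gene-weight vectors (radius 0.2, minimum
  support half the restarts). Each surviving cluster contributes its
  *centrotype* — the member minimizing summed distance to the cluster —
  so reported components are actual solutions, not averages.
* **Conventions.** Columns of `M` have unit L2 norm and their
  largest-magnitude weight is positive; `A` is recomputed as the
  least-squares projection of `X` on the final `M`; components are
  ordered by activity energy.

### Choosing the dimensionality

`sweep_dimensions()` runs the decomposition over a grid and counts, per
dimension, robust components and those that fail to define a multi-gene
set — single-gene components (one gene dominating the squared weight) and
degenerate components (weights already Gaussian, empty membership). Both
are symptoms of over-decomposition: surplus dimensions stabilize around
individual genes or reproducible noise directions.

`select_optimal_dimension()` returns the **largest** dimension at which
every robust component is still a multi-gene component. The largest, not
the smallest: under-decomposition satisfies the equality trivially
(mixtures of modules are never single-gene), so the informative boundary
is where the equality first breaks from above. On synthetic compendia
with eight planted modules, the selector recovers dimension 8 in
essentially every seeded trial. When no dimension satisfies the equality
exactly, the dimension minimizing the single-gene excess is returned
(ties toward the smaller dimension) and flagged approximate.

## From components to iModulons

`threshold_gene_weights()` strips the largest-|weight| genes one at a
time until the remainder passes a D'Agostino K-squared normality test
(p > 1e-4): the surviving weights are the Gaussian "background" and the
stripped genes are the members. The threshold is placed midway between
the smallest stripped and largest surviving absolute weight, so that
membership is exactly the stripped set under a strict comparison. A
`quantile` method (`mean + c * sd`) is available as a fallback for
heavy-tailed components. The K-squared test itself (`dagostino_k2()`) is
implemented from the published skewness and kurtosis transformations and
agrees with independent implementations to ten digits.

Explained variance of a component subset S is
`1 - ||X - M_S A_S||_F^2 / ||X||_F^2`. Per-component values use S = {j};
they need not sum exactly to the all-component value because the
components are only approximately orthogonal, a point the test suite
covers with an explicit tolerance. The package reports both the
per-component and the full-decomposition value; PCA with the same number
of components is an upper bound on the latter, and that ordering is
asserted on every synthetic compendium.

`detect_single_gene()` flags components whose membership is a single gene
or whose top gene carries at least half the squared weight.

## Differential iModulon activity (DIMA)

`differential_activity()` contrasts mean activities between two sample
groups. The null is empirical: absolute activity differences between
biological replicate pairs are pooled and fitted with a log-normal; each
component's p-value is the fitted upper-tail probability of its observed
|difference|, and Benjamini–Hochberg FDR at 0.05 marks significance.

Two numerical choices matter:

* the replicate fit describes a *single-pair* difference, while the
  tested statistic is a difference of group means, so the fitted location
  is rescaled by `sqrt((1/n1 + 1/n2)/2)` — without this the test is so
  conservative that moderate planted shifts go undetected;
* a log-normal is an approximation to the half-normal law that Gaussian
  replicate noise actually induces. The approximation is deliberate (it
  is robust to heavier-tailed replicate noise) but irreducibly imperfect:
  null p-values are near-uniform, not exactly uniform, and calibration is
  therefore validated by the false-flag rate, which stays at or below the
  nominal 5%.

## Regulon enrichment and recall

`enrich_regulons()` tests every (iModulon, regulator) pair with a
one-sided Fisher exact (hypergeometric upper-tail) test. The background
universe is the set of genes the decomposition saw — not the whole
genome — because genes absent from the compendium could never have
entered an iModulon. BH correction runs across the full pair grid, and
the best regulator with q <= 0.05 is attached to the iModulon, upgrading
it to `regulatory`.

Two recall metrics summarize each pair: iModulon recall (shared genes /
iModulon size) and regulon recall (shared genes / regulon size).
`classify_quadrant()` cuts both at 0.6 — the midline convention used when
such scatter plots are drawn in the iModulon literature; the cut is a
parameter — giving `well_matched`, `regulon_subset`, `regulon_discovery`,
or `poorly_matched`.

## The sequence arm

**Operons.** `cluster_operons()` batches genes by accession, sorts by
start, and walks the list: a gene joins the current operon when the
intergenic gap (`next_start - previous_end - 1`) is at most the threshold
and the strand matches. The threshold defaults to 500 bp and strand
awareness to on — both explicit parameters, since published descriptions
of distance-based operon calling rarely pin them down. Overlapping genes
(negative gap) join. The result is always a partition, and raising the
threshold can only merge operons.

**PSSM.** `build_pssm()` counts bases per position over aligned binding
sites, adds a pseudocount (default 0.5), normalizes, and scores against a
mononucleotide background in bits: `log2(p / background)`. The background
source is a *required* argument (sites, promoters, genome, or explicit
frequencies) because "the background" is genuinely ambiguous and the
scores change with the choice. `motif_search()` scans every window at
step 1 on both strands (reverse-complement scanning on by default; TF
sites are double-stranded), returning the best score, its 0-based offset
in input coordinates, and the strand; ties resolve forward-first, then
leftmost. A direct consequence of the log-odds construction is that
background-drawn windows score at most 0 bits in expectation, which the
suite verifies by Monte Carlo. Promoters default to the 300 bp upstream
of an operon's lead gene.

**Classifier.** `evaluate_cv()` predicts regulon membership from motif
scores with elastic-net logistic regression (glmnet; L1:L2 ratio 0.5
fixed, lambda chosen by an internal 3-fold cross-validated AUC over a
log grid 1e-3..100). Class imbalance is handled by SMOTE oversampling of
the minority class (interpolation between a point and one of its 5
nearest minority neighbours) followed by removal of Tomek links, with
*both* members of a link dropped. Cross-validation is fivefold,
stratified, and grouped in *operon space*: operons, labelled positive if
any member gene is positive, are assigned whole to folds, so
co-transcribed genes — which share a promoter and hence a motif score —
never straddle train and test. Resampling is applied to the training
portion of each fold only; resampling before the split would leak
synthetic copies of test points into training. AUC uses the rank
(Mann–Whitney) formulation, and 0.8 is carried as the benchmark a
satisfactory model should reach.

## The synthetic compendium generator

`generate_compendium()` plants `X = M A + E`: disjoint sparse modules
(signed weights uniform in [1, 2]), condition-level activities drawn
i.i.d. standard normal and shared across replicates, replicate-level
jitter whose variance is solved in closed form so the expected
within-condition correlation of expression columns matches a target
`replicate_rho`, and i.i.d. Gaussian noise on the logTPM scale.
Conditions are chunked into projects of four (emulating media types),
the first condition of each project being its reference. The default
shape used throughout the tests — 200 genes, 20 conditions x 3
replicates, 5 modules, noise sd 0.3, rho 0.9 — mirrors, at desk scale,
a compendium of order a hundred samples over tens of conditions from
around a dozen media types.

`generate_genome()` lays genes on accessions with exact within-operon
and between-operon gaps, emits a 300 bp uniform-background promoter per
operon, and can plant one motif instance per selected promoter — sampled
from the PWM (`motif_mode = "sample"`, realistic) or as the consensus
(`"consensus"`, which guarantees the planted window is the top scorer at
its recorded offset; sampled sites occasionally carry enough errors to
lose the maximum to a nearby window, so offset-exactness checks use
consensus planting). `generate_trn_table()` emits regulons with a
controlled overlap fraction and controlled contamination, making
downstream recall values exact by construction.

What the generator deliberately does **not** emulate — and hence what
passing tests do and do not show about real data: count-level (negative
binomial) noise, library-size and batch effects, overlapping regulons,
correlated module activities, non-uniform promoter composition, and
genuine single-gene expression signals. Two consequences are worth
spelling out. First, the over-decomposition signature on synthetic data
is the *degenerate* (Gaussian-weight) component rather than the genuine
single-gene component seen in real compendia; the sweep counts both.
Second, because the planted signal is low-rank, the within-group
correlation of replicate columns concentrates with the number of modules
rather than the number of genes: even at rho 0.95 an occasional condition
with weak activities dips below a 0.80 threshold, so "high-fidelity
replicates are essentially never averaged" is true as a rate, not as a
strict zero.

## Problem sizes and determinism

The test and verification runs use desk-scale sizes chosen to make every
property checkable in seconds to a couple of minutes per stage: 200-gene
compendia for recovery and dimension selection (20 seeds), 60-operon
genomes with 15 positive operons for the classifier benchmark, 50
repetitions for DIMA calibration, 100 random sequences and 10,000
windows for the motif-scan oracles. Every stochastic step takes an
explicit seed; a single master seed fans out to stage-specific seeds via
a stable string hash (`derive_seed()`), so one integer reproduces a full
pipeline run bit for bit — the pipeline manifest records per-file
checksums to make that checkable.

## Known limitations

* The robustness clustering is quadratic in (restarts x dimension);
  at production scale (100 restarts, dimension 100) the distance matrix
  is large, and a chunked implementation would be the next step.
* The log-normal DIMA null is an approximation; with many replicate
  pairs a nonparametric (empirical-quantile) null would be preferable.
* Enrichment treats regulons as flat gene sets; operator strength,
  effector state, and sign of regulation are out of scope.
* The classifier's default feature is the single best motif score per
  operon; window-score quantiles can be added as extra columns, but
  richer sequence features (spacing, palindromicity) are not modelled.
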