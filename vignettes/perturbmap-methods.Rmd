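---
title: "Cell type and spatial prioritization of perturbation responses"
author: "perturbmap developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell type and spatial prioritization of perturbation responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perturbmap)
```

# The problem

When a tissue is perturbed — by injury, a drug, electrical stimulation —
different cell populations and different anatomical regions respond to
different degrees. Single-gene marker tests answer "which genes moved?";
they are poor at answering "which *cells* or *places* moved most?". This
package quantifies the latter as **transcriptional separability**: a cell
type (or a spatial neighbourhood) that responds strongly to a perturbation
becomes easier to tell apart from its unperturbed counterpart in expression
space. Separability is measured as the area under the ROC curve (AUC) of a
random-forest classifier predicting the experimental condition from
expression, evaluated strictly out of sample. An AUC of 0.5 means the two
conditions are locally indistinguishable; an AUC near 1 means a profound
transcriptional response.

Two modes share the same classification core:

* **Cell-type prioritization.** For each annotated cell type, repeatedly
  (50x) draw a balanced subsample of 20 cells per condition, select variable
  features within the subsample, and score a 3-fold cross-validated
  random-forest AUC. The mean over subsamples ranks cell types by response
  magnitude. Fixed-size subsampling is the crucial device: it decouples the
  score from cell-type abundance, so a rare population can outrank an
  abundant one.

* **Spatial prioritization.** Spatial transcriptomics assigns each barcode
  an (x, y) position in a common coordinate frame. For each barcode, take
  its k nearest neighbours *from each condition* (k = 20 by default, so 40
  barcodes per window), withhold condition labels for one fold at a time
  (3-fold stratified CV, so each fold withholds 1/3 of the labels), train
  the forest on the rest, and score the withheld barcodes. The CV is
  repeated 50 times with re-randomized folds and the AUCs averaged, giving
  one number per barcode — an AUC map over the tissue.

# The classifier

No random-forest package is part of this package's dependency footprint, so
the forest is implemented in compiled code and is deliberately boring: CART
trees on bootstrap resamples, Gini impurity, `floor(sqrt(p))` candidate
features per split, class probability equal to the mean leaf class fraction
across 100 trees. Two details deserve explanation:

* **`min_node_size = 10`** (minimal node size to attempt a split; terminal
  nodes may be smaller). This is the probability-forest convention: leaves
  retain graded class fractions instead of pure 0/1 votes, which produces
  better-calibrated rankings for AUC computation on the very small windows
  used here. For tiny windows the threshold is capped at half the training
  size so trees always learn. Set `min_node_size = 2` to grow to purity.

* **Ties.** Tied classifier scores credit 0.5 per tied pair
  (Mann-Whitney midrank convention), and per-fold AUCs are averaged within
  a repeat, which is robust to the 14/13/13 fold-size split of a 40-barcode
  window.

All randomness flows through a package-internal splitmix64 generator seeded
explicitly. Each unit of work (a cell type, a barcode) derives its own
stream by hashing the base seed with its identifier, so results are
bit-identical across platforms, independent of R's RNG state, and invariant
to processing order — adding a cell type never changes another's score.

# Feature selection

Within each subsample or window, features are ranked by the residual of a
locally weighted regression (`lowess`) of log variance on log mean, and the
top `var_quantile` fraction (default 0.5) is kept. This is
coefficient-of-variation detrending: it prefers features that are more
variable than others of comparable abundance. Zero-variance features are
never selected. In the spatial mode the selection is computed once per
window on the pooled 2k barcodes, not per CV repeat: repeats are meant to
average partition noise, not feature-set noise.

# Null calibration, honestly stated

On data with no condition difference the *grand mean* AUC across many units
is within 0.5 ± 0.01 (the acceptance suite checks ± 0.03). A *single*
40-cell window, however, has an across-dataset standard deviation of about
0.08 in its 50-repeat mean AUC: repeating the CV averages fold-partition
noise but cannot remove dataset-level chance separability. Per-barcode null
values of 0.35 or 0.62 are therefore unremarkable; maps should be read as
fields, and the smoothing step exists for exactly this reason.

# The simulator

Validation uses synthetic spatial data with known ground truth, following
the Splat generative hierarchy at its core:

* gene means `lambda_g ~ Gamma(mean_shape = 0.6, mean_rate = 0.3)`;
* library sizes `L_c ~ LogNormal(lib_loc = log(2e4), lib_scale = 0.3)` —
  a deliberately Visium-like scale (median ~20,000 UMIs), since the
  original fit of these parameters to real spatial data cannot be
  reproduced without the primary data; `estimate_splat_params()` provides a
  moment-matching fit to any user count matrix;
* expected counts `mu_gc = lambda_g / sum(lambda) * L_c`; counts are
  Poisson around a gamma-multiplied mean with biological coefficient of
  variation `dispersion = 0.2` (0 gives pure Poisson).

Splat's outlier-gene and dropout submodules are intentionally omitted: the
validation's purpose is spatial differential-expression structure, and those
submodules are orthogonal to it.

Each barcode is placed uniformly in the unit square and assigned one of two
interleaved conditions by a fair coin — mirroring registered tissue sections
from two groups of animals sharing one coordinate frame. A fraction
`de_prob = 0.10` of genes is differentially expressed with log-normal factor
`F_g` (`de_fac_loc = 1.0`, `de_fac_scale = 0.4`, random sign, so up- and
down-regulation mix). The factor is applied to condition-B barcodes as
`F_g ^ intensity(x, y)` — log-linear interpolation between no effect
(intensity 0) and full effect (intensity 1) — before renormalizing each
barcode's expected counts to its library size. Condition-A barcodes keep
their baseline expectation exactly.

Six intensity fields operationalize the validation desiderata — sharp
borders, smooth gradients, and quantitative grading: `null` (intensity 0
everywhere), `half_border` (1 where x > 0.5), `linear_gradient` (intensity
= x), `radial_focus` (cone around the centre), `two_foci_graded` (two foci
with peak intensities 1.0 and 0.5), and `ring` (an annulus). The geometries
are this package's own documented stand-ins — the concrete shapes used in
the original validation are not recoverable from text — and any
user-supplied intensity function can be plugged in instead.

# Smoothing and evaluation

AUC maps are smoothed with two-dimensional locally weighted regression: at
each point of a 50x50 grid, a local linear fit with tricube weights over the
`span = 0.3` fraction of nearest barcodes. Degenerate windows are widened
with a warning, and predictions are clamped to the observed value range, so
the smoothed field never invents values outside the data. Recovery against
ground truth is summarized by (a) the Spearman correlation between
per-barcode AUC and true intensity and (b) the detection AUROC for
classifying barcodes with intensity > 0.5; a pattern counts as *recovered*
when Spearman >= 0.4 and AUROC >= 0.8 (both thresholds exposed).
`concordance()` correlates two score sets matched by barcode or by nearest
coordinate — e.g. cell-type AUCs embedded at spatial positions against the
spatial AUC map.

# Choices made where the design was open

* **Expression transform.** The classifiers are fed
  `log(1 + 1e4 * count / library)` (counts-per-10k log1p), the standard
  transform in this method family; RNA-velocity matrices are accepted as-is
  via `feature_matrix(kind = "velocity")` and bypass normalization.
* **QC boundaries are strict** ("less than 200 genes", "more than 5%
  mitochondrial reads", "less than 5,000 UMIs", "less than 3 cells"):
  boundary values are retained. Mitochondrial genes are identified by a
  configurable ID prefix (default `mt-`), since no canonical list is
  assumed.
* **The window centre is eligible for its own condition's neighbour set**:
  it is a labelled observation like any other, and excluding it would bias
  windows asymmetrically between conditions.
* **Distance ties** in the neighbour search break by lexicographic barcode
  ID, for reproducibility across platforms.
* **"Withholding a proportion of labels"** is realized exactly as
  stratified 3-fold CV: the proportion is 1/n_folds, not an independent
  parameter.
* **Per-barcode AUC summary** is the arithmetic mean of the repeat AUCs;
  all repeat samples are retained in the output for any other summary.
* **Skipped units** (too few cells or barcodes for a balanced window) are
  reported with a reason, never imputed at 0.5, and excluded from smoothing.
* **Condition count.** Each run compares exactly two conditions;
  multi-comparison studies orchestrate pairwise runs (the CLI level).
* **White-matter-style exclusions** rely on anatomical annotation this
  package does not compute; `prioritize-spatial --exclude-barcodes` accepts
  an explicit blacklist instead.
* **Split thresholds** are midpoints between adjacent observed values,
  evaluated at every dense-rank boundary in a node's value span; in an empty
  value gap the threshold may sit at a different midpoint than a textbook
  implementation would choose, but the selected partition is identical.

# What a green test establishes — and what it does not

The simulator emulates overdispersed UMI counts with a spatially graded,
multiplicative two-condition difference under uniform spatial sampling. It
does **not** emulate segmentation errors, section-to-section misregistration,
batch effects, cell-type mixtures within barcodes, dropout beyond
gamma-Poisson sparsity, or non-multiplicative responses. A green validation
therefore establishes that the method recovers spatially structured
separability of the stated kind at the stated scale — 1,000 barcodes by
1,000 genes in the desk-scale suite, against 5,000 barcodes at full scale —
not that it is robust to every artefact of real spatial data. The paper-scale
defaults (`splat_params()` with 5,000 barcodes) are retained for users who
want the full-size run.

# Known limitations

* Two-dimensional coordinates only; 3D neighbourhoods are out of scope.
* The spatial null band for a single barcode is wide (see calibration
  above); significance testing of AUC maps is intentionally left to the
  user.
* The forest is binary-condition only; more than two conditions require
  pairwise runs.
* `estimate_splat_params()` is a moment matcher, not a likelihood fit; it
  recovers scale, not fine structure.
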