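---
title: "Methods: image features, stacked risk scores and survival stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image features, stacked risk scores and survival stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(wsirisk)
```

This vignette is the package's own account of its models, parameter
choices and limitations. Nothing stated here is an empirical claim beyond
what the test suite and `scripts/acceptance.R` compute.

## The problem

Hepatocellular carcinoma recurs after resection in roughly half of
patients. Two data sources plausibly carry prognostic signal at low cost:
the morphology of tumor nuclei visible in routine H&E diagnostic slides,
and the expression of immune marker genes measured by RNA-seq. The
pipeline turns each source into a per-patient risk score for
recurrence-free survival (RFS), combines the scores, and evaluates whether
the combination predicts better than either source alone.

## Synthetic data: what it emulates, and what it does not

Real cohorts of this kind cannot be shipped with a package, so the first
module generates both layers of data with known ground truth.

**Slides.** A tile is an eosin-toned background with low-frequency texture
(Gaussian-blurred white noise, sd 0.05 of the intensity range, blur radius
8 px), on which `n_nuclei` rotated ellipses are planted with
hematoxylin-toned fill, then per-pixel Gaussian sensor noise (sd 0.02) is
added and clipped. The two stain tones are forward-synthesized from the
standard Ruifrok–Johnston H&E optical-density vectors (hematoxylin density
0.9, eosin 0.35), so color deconvolution is exact by construction rather
than approximately right for some arbitrary palette. Nucleus semi-axes are
LogNormal with mean `axis_mean` (default 14 and 9 px, a plausible nuclear
scale for a 40X-magnification crop) and coefficient of variation `h`, the
single heterogeneity dial. LogNormal rather than Normal keeps every
descriptor strictly positive, so the min–max-rate statistic is always
defined; `h = 0` degenerates to identical ellipses, giving exact
ground-truth identities (every mrate equals 1). Placement is rejection
sampling with a bounded attempt budget; by default nuclei may not overlap,
and the placement margin keeps every ellipse fully inside the tile.

What the generator deliberately does *not* model: stain variation between
slides, touching and overlapping nuclei in clusters, non-elliptical and
lobulated nuclei, multiple tissue classes, pyramid WSI formats. Passing the
segmentation tests therefore shows the pipeline is correct on
well-separated elliptical nuclei of realistic contrast — not that it
matches pathologist-grade segmentation on real tissue.

**Cohorts.** Expression of 66 marker genes is multivariate normal on the
log(FPKM + 1) scale with a configurable covariance (default AR(1),
correlation 0.5), truncated at zero. When no slides are supplied, the 153
image features are correlated Gaussians under the same feature names, so
the survival machinery can be exercised at scale without image processing.
Event times follow a Weibull-baseline proportional-hazards model inverted
in closed form; censoring is the minimum of an exponential
loss-to-follow-up draw and an administrative cap at 3,650 days (the two
causes are not distinguished). The default conditions mirror the study
scale: 231 patients, and a censoring rate of 1/1,110 per day calibrated so
the realized event fraction is close to 53%. The default sparse truth has
four active predictors — one protective image heterogeneity feature
(`area_mrate`, negative coefficient: more heterogeneous nuclei, worse
prognosis) and three genes (one hazardous, two protective), each with
|coefficient| ≈ 0.5 on roughly unit-variance columns. These effect sizes
were chosen once so that the stacked integration evaluates in the
mid-0.6s C-index range typical of prognostic models of this kind; they are
a simulation condition, not a reproduction claim.

A single master seed feeds named substreams (`placement`, `stain-noise`,
`expression`, `survival`, `wsi-sampling`, `cv-folds`, `split`, `perm-*`),
so any stage can be regenerated independently and every result is
bit-reproducible from one integer.

## Slide features

The 153-entry vector decomposes as 18 + 27 × 5.

**Global gray-level features (18).** The tissue mask is Otsu thresholding
of ITU-R 601 luminance keeping the darker (stained) class, closed with a
5-px disc. The foreground block is chosen by a coverage-maximizing scan on
a stride grid (stride = block/4, row-major, first maximum wins) — the
protocol crops a 32,000² block on real slides, capped to the image for
synthetic tiles. The block is shrunk by area averaging to the global ROI
and summarized by the standard radiomics first-order panel of exactly 18
statistics; entropy and uniformity use a fixed bin width of 25 gray
levels, so a constant ROI gives entropy 0 and uniformity 1 exactly.

**Nucleus shape features (135).** Segmentation: color deconvolution
(`OD = −log10((I+1)/256)`, concentrations = OD · M⁻¹ with the H&E + residual
stain matrix), 3×3 Laplacian sharpening of the hematoxylin channel, Otsu on
the rescaled result, intersection with an adaptive Gaussian-weighted
local-mean threshold (window 51 px, offset 2 gray levels), an absolute
hematoxylin-concentration floor of 0.15 OD (so sensor noise on an
unstained tile can never masquerade as nuclei), hole filling, opening
(3-px disc), hole filling again, and watershed separation of touching
nuclei on the distance map (tolerance 1.5 px — two non-overlapping nuclei
can still share an 8-connected raster boundary, and the watershed undoes
exactly that merge without splitting single wobbly nuclei). Components
below 40 px are dropped. Components touching the block border are discarded
by default because their shapes are truncated by the crop; this matters on
small synthetic tiles where border contact is proportionally frequent.
Each region gets a direct least-squares (Fitzgibbon/Halir–Flusser) ellipse
fit to its contour — with the second-moment equivalent ellipse as a
numerical fallback — and a convex hull.

The 27 descriptors are area, perimeter, perimeter/area, equivalent
diameter, circularity, convex area, solidity, convexity, extent,
eccentricity, major/minor axis, aspect ratio, ellipse-fit residual,
max/min Feret diameter and their ratio, bounding-box aspect, compactness,
2-D sphericity, and the seven Hu moment invariants. Three conventions keep
every descriptor strictly positive so that mrate is always defined: Hu
moments are exported as `40 − sign(h)·log10(|h| + 1e−12)`; the ellipse
residual carries a 0.01-px floor; Feret breadths measured between
supporting lines through pixel centers are widened by one pixel so a
one-pixel-thick shape has unit, not zero, breadth. Convex area is the
count of pixel centers inside or on the hull polygon, which makes
`solidity = 1` exact for convex raster shapes.

Aggregation emits mean, sd, min, max and `mrate = min/max` per descriptor.
Protocol parameters (20 sampled blocks, 20 nuclei per block, pooling at
most 400 nuclei) are configurable and capped to the tile; when a block
yields fewer than 20 nuclei all are kept, and a slide with no detectable
nuclei anywhere raises an explicit "no nuclei sampled" condition rather
than imputing.

Whether the ellipse/hull fitting should *replace* the segmented mask or
only inform descriptors is genuinely open; here descriptors are computed
jointly from the mask, the hull and the fitted ellipse, and the mask is
never altered.

## Survival modeling

**Base learners.** L1-penalized Cox partial likelihood (glmnet) over 100
log-spaced penalties from the null-model λ_max down, with the penalty
chosen by minimum mean 3-fold cross-validated deviance (the minimum rule,
not 1-SE; a switch is exposed). The grid floor defaults to 0.01·λ_max: on
cohorts of a few hundred patients the cross-validated optimum sits well
inside the grid (selected penalties in the tests are an order of magnitude
above the floor), while the near-saturated tail below it is by far the most
expensive part of the path to fit. Features are standardized internally
with coefficients reported on the original scale; constant columns are
dropped with a warning; a single-column design falls back to the
unpenalized Cox MLE, which is the small-penalty limit. Ties use Efron's
approximation throughout.

**Integrations.** Single-domain, pooled-features, or stacked: one base
learner per domain, an unpenalized second-level Cox on the training-split
domain scores (optionally with pairwise score products as interaction
terms), and the composite linear predictor as the final score. Fitting the
second level on the same training split as the base learners is mildly
optimistic; all comparisons rest on the held-out test split, which is
untouched by either level.

**Evaluation.** Twenty random 2:1 splits (|train| = round(2n/3): 154/77 at
n = 231; simple random sampling, no stratification). Harrell's C-index
counts a pair comparable when the shorter observed time is an event (a
censored subject tied in time with an event is taken to outlive it), with
tied scores worth 1/2. Time-dependent AUC is the IPCW cumulative/dynamic
estimator with censoring weights from a Kaplan–Meier fit of the censoring
distribution on the *training* split; the default grid is the test
event-time quantiles at probabilities 0.1–0.8, and the summary is the
unweighted mean over the grid. The final model is the simplest (fewest
nonzero coefficients, both levels of a stacked model counted) among those
with test C-index between the median and the upper quartile (inclusive,
linear-interpolation quantiles); ties go to the higher C-index, then the
lower split id.

**Permutation significance.** The (time, event) pairs are jointly
reshuffled against the covariate rows — preserving the marginal censoring
pattern — the full evaluation loop is re-run per permutation, and a normal
distribution is fitted to the permuted mean C-indices; the p-value is the
upper tail at the observed mean. The full protocol uses 100 permutations;
desk-scale runs (tests, the acceptance script) use 20 permutations of 5
splits, which is ample to locate the null mean within ±0.02 of 1/2. A
zero-variance null is reported as an explicit error rather than p = 0.

## Stratification

The median split labels scores at or below the sample median (midpoint of
order statistics for even n) as lower-risk, so 231 distinct scores give
116 lower / 115 higher. Kaplan–Meier curves use Greenwood variance with
log(−log) confidence bands; the median RFS is the first time the curve
drops to 0.5 or below, and its confidence limits invert the pointwise
bands (the standard band-inversion construction; the method behind a
published median CI is rarely stated, and this choice matches common
survival software). The log-rank test is the two-group 1-df hypergeometric
form; the continuous-score hazard ratio is a univariate Cox fit with Wald
interval.

## Numerical choices and degenerate inputs

* Otsu thresholding maximizes between-class variance by exhaustive scan
  over all 256 levels; ties break to the lowest level; a one-bin histogram
  (constant image) is a "degenerate histogram" error, propagated by the
  tissue mask.
* Coordinates are 0-based, row-major, half-open throughout the image code.
* A contour with fewer than five points cannot support an ellipse fit and
  the region is skipped; a conic fit that is not an ellipse falls back to
  the moment ellipse.
* All-censored outcomes, zero-variance scores, empty nucleus sets and
  missing feature columns raise explicit errors; nothing is silently
  imputed.

## Problem sizes used in tests

The suite exercises slides of 256–320 px with 15–40 nuclei and sampling
blocks of 160 px, cohorts of 231–5,000 patients, 20-split evaluations, and
permutation runs of 20 × 5; these sizes were chosen to make the full suite
comfortably reproducible on a single CPU while keeping every statistical
check well-powered. The same code paths scale to full-protocol sizes
(1,000-px blocks, 100 permutations of 20 splits) by changing only
configuration values.

## Known limitations

* The generator's nuclei are isolated ellipses; segmentation performance on
  real, touching, irregular nuclei is out of scope and untested here.
* The stacked second level is fitted on the same split as its base
  learners (see above).
* Statistical comparison *between* integration strategies is not
  implemented: the repeated splits share patients, violating independence
  assumptions of naive tests.
* Competing risks, treatment adjustment and more flexible learners
  (e.g. random survival forests) are intentionally outside the package's
  scope.
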