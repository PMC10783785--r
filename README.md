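# wsirisk

Image-based recurrence-free-survival (RFS) risk stratification for
hepatocellular carcinoma, rebuilt as a fully simulation-backed R pipeline.

Surgically treated liver cancer recurs in roughly half of patients, and
conventional staging predicts recurrence poorly. This package implements a
prognostic workflow that combines two inexpensive data sources — nuclear
morphology read from H&E-stained whole-slide images (WSI) and the expression
of immune marker genes — into a single risk score, and quantifies how well
that score separates patients who recur early from those who do not.
Because the clinical cohort itself cannot be redistributed, the package
ships a synthetic-data module that generates H&E-like tiles with known
nuclei and cohorts with known survival structure, so every stage of the
pipeline is testable end to end on a laptop.

## What it computes

**Slide features.** Each slide yields a 153-entry feature vector:

* 18 first-order gray-level statistics of a global region of interest
  (energy, entropy, percentiles, variance, uniformity, ...), computed on an
  area-averaged 8-bit luminance ROI.
* 135 nucleus-shape features: nuclei are segmented by color deconvolution
  into the hematoxylin channel, Laplacian sharpening, Otsu plus adaptive
  thresholding, and morphological cleanup; each nucleus gets 27 shape
  descriptors (area, perimeter, circularity, solidity, fitted-ellipse axes,
  Feret diameters, Hu moments, ...), and each descriptor is aggregated
  across sampled nuclei as mean, sd, min, max and the min–max rate

  `mrate = min / max ∈ (0, 1]`,

  a per-slide contrast statistic: small mrate means highly heterogeneous
  nuclear morphology, a classic malignancy signal.

**Risk modeling.** Per data domain (clinicopathologic variables, image
features, gene expression) a Lasso-penalized Cox model
`h(t|x) = h0(t) exp(βᵀx)` is fitted with 3-fold cross-validated penalty
selection; domain risk scores `s = Xβ` are combined by an unpenalized
second-level Cox model ("stacked" integration). Models are evaluated over
20 random 2:1 train/test splits with Harrell's C-index and IPCW
time-dependent AUC; a final model is the simplest one whose test C-index
falls between the median and upper quartile of the splits. Significance is
assessed by reshuffling (time, event) against the covariates and fitting a
normal distribution to the permuted mean C-indices.

**Stratification.** The cohort is split at the median score; the package
reports per-group Kaplan–Meier curves with median RFS and 95% CI
(log(−log) Greenwood bands), the two-group log-rank test, and the per-unit
hazard ratio of the continuous score.

## Worked example

```r
library(wsirisk)

# an H&E-like tile with 40 nuclei of mild shape heterogeneity
slide <- generate_slide(slide_sim_params(image_size = 320, n_nuclei = 40,
                                         heterogeneity = 0.1, seed = 7))
feats <- extract_slide_features(slide,
          feature_config(sample_block_size = 160, n_blocks = 20), seed = 3)
round(feats[c("area_mean", "area_mrate", "major_axis_mean", "solidity_mean")], 3)
#>       area_mean      area_mrate major_axis_mean   solidity_mean
#>         393.694           0.491          27.483           1.000

# a 231-patient cohort with four true predictors and ~53% events
cohort <- generate_cohort(cohort_sim_params(seed = 1))
spec   <- integration_spec("stacked", c("image", "genes"))
ev     <- evaluate_integration(cohort, spec, n_splits = 20, seed = 42)
round(ev$mean_cindex, 3)
#> [1] 0.665

final  <- select_final_model(ev)
scores <- risk_score(final$model, cohort_domains(cohort, spec$domains))
strat  <- stratify_cohort(scores, cohort$time, cohort$event)
c(strat$n_lower, strat$n_higher)          # 116 115
round(strat$hr$hr, 2)                     # 3.37  (hazard ratio per unit score)
round(strat$km$lower$median)              # 786   (median RFS, lower-risk group)
round(strat$km$higher$median)             # 388   (median RFS, higher-risk group)
```

The planted truth in the default cohort is one protective image
heterogeneity feature plus three genes; the stacked image + genes
integration typically evaluates around C ≈ 0.65 on test splits, clearly
above the single-domain models, and the median split produces strongly
separated Kaplan–Meier curves.

The `analysis/` directory contains the same workflow as numbered narrative
scripts (simulate slides → extract features → simulate cohort → compare
integrations → permutation test → stratify), writing tables under
`results/`.

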