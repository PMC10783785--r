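#!/usr/bin/env Rscript
# Characterize the final risk score: median split into lower/higher-risk
# subgroups, Kaplan-Meier median RFS with 95% CI, log-rank comparison, and
# the per-unit hazard ratio of the continuous score.

suppressMessages(library(wsirisk))

seed <- 20260920L
cohort <- generate_cohort(cohort_sim_params(seed = seed))
spec <- integration_spec("stacked", c("image", "genes"))

ev <- evaluate_integration(cohort, spec, n_splits = 20,
                           seed = substream_seed(seed, "eval-stacked_img_gen"),
                           compute_auc = FALSE)
fm <- select_final_model(ev)
scores <- risk_score(fm$model, cohort_domains(cohort, spec$domains))
st <- stratify_cohort(scores, cohort$time, cohort$event)

fmt_med <- function(km) sprintf("%.0f (95%% CI %.0f-%s)", km$median,
                                km$median_lcl,
                                ifelse(is.na(km$median_ucl), "NR",
                                       sprintf("%.0f", km$median_ucl)))
res <- list(
  n_lower = st$n_lower, n_higher = st$n_higher,
  median_rfs_lower = st$km$lower$median,
  median_rfs_lower_ci = c(st$km$lower$median_lcl, st$km$lower$median_ucl),
  median_rfs_higher = st$km$higher$median,
  median_rfs_higher_ci = c(st$km$higher$median_lcl, st$km$higher$median_ucl),
  logrank_chisq = st$logrank$chisq, logrank_p = st$logrank$p_value,
  hr = st$hr$hr, hr_ci = c(st$hr$lcl, st$hr$ucl), hr_p = st$hr$p_value,
  final_model_split = fm$split_id, final_model_cindex = fm$cindex)
jsonlite::write_json(res, "results/stratification.json",
                     auto_unbox = TRUE, digits = NA)

dir.create("scratch", showWarnings = FALSE)
grDevices::png("scratch/km_stratification.png", 900, 700, res = 120)
plot(st, main = "RFS by risk-score subgroup (median split)")
invisible(grDevices::dev.off())

cat(sprintf("Subgroups: lower n = %d, higher n = %d\n", st$n_lower, st$n_higher))
cat("Median RFS lower-risk:", fmt_med(st$km$lower), "days\n")
cat("Median RFS higher-risk:", fmt_med(st$km$higher), "days\n")
cat(sprintf("Log-rank chi-square %.2f, p = %.2g\n", st$logrank$chisq,
            st$logrank$p_value))
cat(sprintf("Hazard ratio per unit score: %.3f (95%% CI %.3f-%.3f), p = %.2g\n",
            st$hr$hr, st$hr$lcl, st$hr$ucl, st$hr$p_value))
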