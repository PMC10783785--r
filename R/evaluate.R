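#' Random train/test split of a cohort
#'
#' Simple random sampling without replacement, no stratification;
#' `|train| = round(train_frac * n)`. Deterministic given the seed.
#'
#' @param n cohort size (>= 3).
#' @param train_frac training fraction (default 2/3; 231 patients split
#'   154/77).
#' @param seed seed for the `"split"` substream.
#' @return list with integer vectors `train` and `test`.
#' @export
split_cohort <- function(n, train_frac = 2 / 3, seed = 1L) {
  stopifnot(n >= 3, train_frac > 0, train_frac < 1)
  n_train <- round(train_frac * n)
  tr <- with_substream(seed, "split", sample.int(n, n_train))
  list(train = sort(tr), test = sort(setdiff(seq_len(n), tr)))
}

#' Specify a data-integration strategy
#'
#' @param mode `"single"` (one domain), `"pooled"` (Lasso-Cox on the
#'   concatenated feature matrix) or `"stacked"` (domain-wise Lasso-Cox
#'   scores combined by an unpenalized second-level Cox model).
#' @param domains character vector of participating domains among
#'   `"clin"`, `"image"`, `"genes"`; stacked mode needs at least 2.
#' @param include_interactions in stacked mode, add pairwise products of
#'   domain scores to the second level.
#' @return list of class `integration_spec`.
#' @export
integration_spec <- function(mode = c("stacked", "single", "pooled"),
                             domains = c("image", "genes"),
                             include_interactions = FALSE) {
  mode <- match.arg(mode)
  domains <- match.arg(domains, c("clin", "image", "genes"),
                       several.ok = TRUE)
  if (mode == "single" && length(domains) != 1)
    stop("single-domain mode takes exactly one domain")
  if (mode == "stacked" && length(domains) < 2)
    stop("stacked mode needs at least two domains")
  structure(list(mode = mode, domains = domains,
                 include_interactions = isTRUE(include_interactions)),
            class = "integration_spec")
}

fit_integration <- function(spec, domains_train, time, event, seed) {
  if (spec$mode == "stacked") {
    fit_stacked_cox(domains_train, time, event, seed = seed,
                    include_interactions = spec$include_interactions)
  } else {
    X <- do.call(cbind, domains_train)
    fit_lasso_cox(X, time, event, seed = seed,
                  domain = if (spec$mode == "single") spec$domains else "pooled")
  }
}

score_integration <- function(spec, model, domains_mat) {
  if (spec$mode == "stacked") risk_score(model, domains_mat)
  else risk_score(model, do.call(cbind, domains_mat))
}

#' Evaluate an integration strategy over repeated random splits
#'
#' For each of `n_splits` random 2:1 train/test splits: fit the integration
#' on the training patients, score the test patients, and record Harrell's
#' C-index and the time-dependent AUC curve on the test set. The headline
#' summary is the mean test C-index across splits.
#'
#' @param cohort a `cohort` (or a list with `time`, `event` and matrices
#'   for the requested domains).
#' @param spec an [integration_spec()].
#' @param n_splits number of repeated random splits (default 20).
#' @param seed master seed; split `s` uses substream `"eval-split-<s>"`.
#' @param train_frac training fraction.
#' @param compute_auc also compute the time-dependent AUC per split.
#' @return object of class `integration_eval`: list with `splits` (each:
#'   `split_id`, `train`, `test`, `model`, `cindex`, `td_auc`),
#'   `mean_cindex`, `spec`, `seed`.
#' @export
evaluate_integration <- function(cohort, spec, n_splits = 20L, seed = 1L,
                                 train_frac = 2 / 3, compute_auc = TRUE) {
  doms <- cohort_domains(cohort, spec$domains)
  n <- length(cohort$time)
  splits <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    sseed <- substream_seed(seed, paste0("eval-split-", s))
    idx <- split_cohort(n, train_frac, seed = sseed)
    dtr <- lapply(doms, function(M) M[idx$train, , drop = FALSE])
    dte <- lapply(doms, function(M) M[idx$test, , drop = FALSE])
    model <- fit_integration(spec, dtr, cohort$time[idx$train],
                             cohort$event[idx$train], seed = sseed)
    sc <- score_integration(spec, model, dte)
    ci <- tryCatch(
      harrell_cindex(sc, cohort$time[idx$test], cohort$event[idx$test]),
      error = function(e) NA_real_)
    ta <- if (compute_auc) tryCatch(
      time_dependent_auc(sc, cohort$time[idx$train], cohort$event[idx$train],
                         cohort$time[idx$test], cohort$event[idx$test]),
      error = function(e) NULL) else NULL
    splits[[s]] <- list(split_id = s, train = idx$train, test = idx$test,
                        model = model, cindex = ci, td_auc = ta)
  }
  structure(list(splits = splits,
                 mean_cindex = mean(vapply(splits, `[[`, 0, "cindex"),
                                    na.rm = TRUE),
                 spec = spec, seed = seed),
            class = "integration_eval")
}

model_size <- function(model) {
  if (inherits(model, "stacked_model")) model$n_nonzero else model$n_nonzero
}

#' Select the final model from repeated-split evaluations
#'
#' The final model is the simplest model (fewest nonzero coefficients,
#' counting both levels of a stacked model) among those whose test C-index
#' lies between the median and the upper quartile of the split C-indices
#' (inclusive; linear-interpolation quantiles). Ties go to the higher
#' C-index, then to the lower split id.
#'
#' @param evaluation an `integration_eval`.
#' @return the chosen split entry (list with `split_id`, `model`,
#'   `cindex`, ...).
#' @export
select_final_model <- function(evaluation) {
  splits <- evaluation$splits
  stopifnot(length(splits) >= 1)
  C <- vapply(splits, `[[`, 0, "cindex")
  qs <- stats::quantile(C, c(0.5, 0.75), names = FALSE, type = 7, na.rm = TRUE)
  elig <- which(C >= qs[1] - 1e-12 & C <= qs[2] + 1e-12)
  if (!length(elig)) elig <- which.min(abs(C - qs[1]))
  size <- vapply(splits[elig], function(s) model_size(s$model), 0)
  ord <- order(size, -C[elig], vapply(splits[elig], `[[`, 0, "split_id"))
  splits[[elig[ord[1]]]]
}

#' Permutation test of an integration's predictive capacity
#'
#' Repeats the full model-development loop on data whose (time, event)
#' pairs have been jointly reshuffled against the covariates (preserving
#' the marginal censoring pattern), records the mean test C-index of each
#' permutation, fits a normal distribution to the null sample by moment
#' matching, and reports the one-sided p-value of the observed mean
#' C-index.
#'
#' @param cohort a `cohort`.
#' @param spec an [integration_spec()].
#' @param n_perm number of permutations (the full protocol uses 100).
#' @param n_splits random splits per permutation.
#' @param seed master seed (substreams `"perm-<p>"` and `"perm-eval-<p>"`).
#' @param observed optional precomputed observed mean C-index; when `NULL`
#'   it is computed with [evaluate_integration()].
#' @return object of class `permutation_result`: `observed`, `null_cindex`
#'   (length `n_perm`), `mu`, `sigma`, `p_value`.
#' @export
permutation_test <- function(cohort, spec, n_perm = 100L, n_splits = 20L,
                             seed = 1L, observed = NULL) {
  n <- length(cohort$time)
  if (is.null(observed)) {
    observed <- evaluate_integration(cohort, spec, n_splits = n_splits,
                                     seed = substream_seed(seed, "observed"),
                                     compute_auc = FALSE)$mean_cindex
  }
  null_c <- vapply(seq_len(n_perm), function(p) {
    perm <- with_substream(seed, paste0("perm-", p), sample.int(n))
    ch <- cohort
    ch$time <- cohort$time[perm]
    ch$event <- cohort$event[perm]
    evaluate_integration(ch, spec, n_splits = n_splits,
                         seed = substream_seed(seed, paste0("perm-eval-", p)),
                         compute_auc = FALSE)$mean_cindex
  }, numeric(1))
  mu <- mean(null_c)
  sigma <- stats::sd(null_c)
  if (!is.finite(sigma) || sigma == 0) stop("degenerate null: zero variance")
  structure(list(observed = observed, null_cindex = null_c,
                 mu = mu, sigma = sigma,
                 p_value = 1 - stats::pnorm((observed - mu) / sigma),
                 n_perm = n_perm, n_splits = n_splits, seed = seed),
            class = "permutation_result")
}
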