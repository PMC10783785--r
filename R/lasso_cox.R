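#' Fit an L1-penalized Cox model with cross-validated penalty
#'
#' Fits the Lasso-penalized Cox partial likelihood over a log-spaced penalty
#' grid (100 values from the null-model `lambda_max` down to
#' `lambda_min_ratio * lambda_max`) and selects the penalty minimizing the mean
#' 3-fold cross-validated partial-likelihood deviance. Features are
#' standardized internally; coefficients are reported on the original
#' scale. Fold assignment draws from the `"cv-folds"` substream of `seed`.
#'
#' Constant feature columns are dropped with a warning. A design with a
#' single (non-constant) column is fitted by the unpenalized Cox MLE — the
#' small-penalty limit of the Lasso path.
#'
#' @param X numeric matrix, patients x features, with column names.
#' @param time,event survival outcome (days; event 1 = recurrence).
#' @param n_folds CV folds (default 3).
#' @param lambda optional: a scalar penalty (fit directly, no CV) or a
#'   decreasing grid to cross-validate over.
#' @param lambda_min_ratio smallest grid penalty as a fraction of the
#'   null-model `lambda_max` (default 0.01; the cross-validated optimum
#'   sits well inside the grid on cohorts of this size, and the saturated
#'   small-penalty tail is costly to fit).
#' @param seed seed for the CV fold substream.
#' @param domain tag carried on the model (`"clin"`, `"image"`, `"genes"`,
#'   `"pooled"`, ...).
#' @return object of class `risk_model`: list with `feature_names`, `beta`
#'   (named, dense, zeros included), `lambda`, `domain`, `n_nonzero`.
#' @export
fit_lasso_cox <- function(X, time, event, n_folds = 3L, lambda = NULL,
                          seed = 1L, domain = "features",
                          lambda_min_ratio = 0.01) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(time), length(time) == length(event),
            !is.null(colnames(X)))
  if (sum(event) < 2) stop("need at least 2 events to fit a Cox model")
  keep <- apply(X, 2, function(x) stats::sd(x) > 0)
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " constant feature column(s): ",
            paste(utils::head(colnames(X)[!keep], 5), collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  if (ncol(X) == 0) stop("no non-constant features left")
  y <- survival::Surv(time, event)

  if (ncol(X) == 1) {
    if (!is.null(lambda) && any(lambda > 1e-8))
      warning("single-feature design: fitting the unpenalized Cox MLE")
    cf <- survival::coxph(y ~ X[, 1], ties = "efron")$coefficients
    beta <- stats::setNames(as.numeric(cf), colnames(X))
    return(new_risk_model(beta, lambda = 0, domain = domain))
  }

  if (!is.null(lambda) && length(lambda) == 1) {
    fit <- glmnet::glmnet(X, y, family = "cox", standardize = TRUE,
                          lambda = c(lambda * 1.0001, lambda))
    beta <- stats::setNames(as.numeric(fit$beta[, 2]), rownames(fit$beta))
    return(new_risk_model(beta, lambda = lambda, domain = domain))
  }

  foldid <- with_substream(seed, "cv-folds",
                           sample(rep_len(seq_len(n_folds), nrow(X))))
  cv <- withCallingHandlers(
    glmnet::cv.glmnet(X, y, family = "cox", standardize = TRUE,
                      foldid = foldid, lambda = lambda,
                      nlambda = 100, lambda.min.ratio = lambda_min_ratio),
    warning = function(w) {
      # the path is truncated where the saturated Cox fit degenerates at
      # very small penalties; CV never selects that end
      if (grepl("Numerical error|Convergence for .* not reached",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  cf <- as.matrix(stats::coef(cv, s = "lambda.min"))
  beta <- stats::setNames(as.numeric(cf), rownames(cf))
  new_risk_model(beta, lambda = cv$lambda.min, domain = domain)
}

new_risk_model <- function(beta, lambda, domain) {
  structure(list(feature_names = names(beta), beta = beta,
                 lambda = lambda, domain = domain,
                 n_nonzero = sum(beta != 0)),
            class = "risk_model")
}

#' Linear risk score of a fitted model
#'
#' `s = X beta` over the model's named features; no intercept.
#'
#' @param model a `risk_model`.
#' @param X matrix containing all model feature columns (by name).
#' @return numeric vector of per-patient scores.
#' @export
risk_score <- function(model, X) {
  UseMethod("risk_score")
}

#' @export
risk_score.risk_model <- function(model, X) {
  X <- as.matrix(X)
  miss <- setdiff(model$feature_names, colnames(X))
  if (length(miss)) stop("missing feature column(s): ",
                         paste(utils::head(miss, 5), collapse = ", "))
  drop(X[, model$feature_names, drop = FALSE] %*% model$beta)
}

#' @export
risk_score.stacked_model <- function(model, X) {
  # X: named list of domain matrices
  sc <- vapply(names(model$base_models),
               function(d) risk_score(model$base_models[[d]], X[[d]]),
               numeric(nrow(X[[1]])))
  colnames(sc) <- names(model$base_models)
  Z <- sc
  if (model$include_interactions && ncol(sc) >= 2) {
    cmb <- utils::combn(colnames(sc), 2)
    for (k in seq_len(ncol(cmb))) {
      Z <- cbind(Z, sc[, cmb[1, k]] * sc[, cmb[2, k]])
      colnames(Z)[ncol(Z)] <- paste0(cmb[1, k], ":", cmb[2, k])
    }
  }
  cf <- model$top_coef
  drop(Z[, names(cf), drop = FALSE] %*% cf)
}

#' Fit a stacked (two-level) risk model
#'
#' One Lasso-Cox base learner per domain; their training risk scores become
#' covariates of an unpenalized second-level Cox model (Efron ties).
#' Base-learner score columns that are constant on the training data (fully
#' shrunk base models) are excluded from the second level.
#'
#' @param domains named list of training design matrices.
#' @param time,event training outcome.
#' @param seed seed (per-domain CV folds use substreams `"cv-<domain>"`).
#' @param include_interactions add pairwise products of domain scores.
#' @return object of class `stacked_model` with `base_models`, `top_coef`,
#'   `include_interactions`, `n_nonzero` (base nonzeros + top coefficients).
#' @export
fit_stacked_cox <- function(domains, time, event, seed = 1L,
                            include_interactions = FALSE) {
  stopifnot(length(domains) >= 2, !is.null(names(domains)))
  base <- lapply(names(domains), function(d)
    fit_lasso_cox(domains[[d]], time, event,
                  seed = substream_seed(seed, paste0("cv-", d)), domain = d))
  names(base) <- names(domains)
  sc <- vapply(names(base), function(d) risk_score(base[[d]], domains[[d]]),
               numeric(length(time)))
  colnames(sc) <- names(base)
  Z <- sc
  if (include_interactions) {
    cmb <- utils::combn(colnames(sc), 2)
    for (k in seq_len(ncol(cmb))) {
      Z <- cbind(Z, sc[, cmb[1, k]] * sc[, cmb[2, k]])
      colnames(Z)[ncol(Z)] <- paste0(cmb[1, k], ":", cmb[2, k])
    }
  }
  ok <- apply(Z, 2, function(x) stats::sd(x) > 0)
  cf <- numeric(0)
  if (any(ok)) {
    df <- as.data.frame(Z[, ok, drop = FALSE])
    fit <- survival::coxph(survival::Surv(time, event) ~ ., data = df,
                           ties = "efron")
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    names(cf) <- colnames(Z)[ok]
  }
  structure(list(base_models = base, top_coef = cf,
                 include_interactions = isTRUE(include_interactions),
                 n_nonzero = sum(vapply(base, function(m) m$n_nonzero, 0L)) +
                   sum(cf != 0)),
            class = "stacked_model")
}
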