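#' Parameters for the simulated RFS cohort
#'
#' Emulates the study cohort structure: per-patient clinicopathologic
#' covariates, a 66-gene log-scale immune-marker expression profile with a
#' configurable covariance, 153 image features, and recurrence-free survival
#' generated from a sparse Cox model with a Weibull baseline hazard and
#' independent censoring (exponential loss-to-follow-up plus an
#' administrative cap at study end).
#'
#' Defaults are the study conditions: 231 patients, 66 marker genes, a true
#' coefficient vector with four active predictors (one image heterogeneity
#' feature with a protective sign and three genes, one hazardous and two
#' protective), and a censoring rate calibrated so the realized event
#' fraction is close to 53 percent.
#'
#' @param n_patients cohort size, at least 2.
#' @param n_genes number of marker genes.
#' @param gene_cov `n_genes x n_genes` symmetric positive-semidefinite
#'   covariance of log-expression; default AR(1) with correlation 0.5.
#' @param gene_mean mean log-expression per gene (recycled).
#' @param true_beta named sparse coefficient vector over image-feature and
#'   gene column names; names must match generated columns.
#' @param baseline_shape,baseline_scale Weibull baseline-hazard parameters,
#'   time in days.
#' @param censor_rate rate (per day) of independent exponential censoring.
#' @param admin_censor_time administrative censoring cap in days (`Inf` to
#'   disable).
#' @param seed master seed; substreams `"expression"`, `"covariates"`,
#'   `"image-features"` and `"survival"` are derived from it.
#' @return object of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_patients = 231L,
                              n_genes = 66L,
                              gene_cov = NULL,
                              gene_mean = 2,
                              true_beta = NULL,
                              baseline_shape = 1.1,
                              baseline_scale = 900,
                              censor_rate = 1 / 1110,
                              admin_censor_time = 3650,
                              seed = 1L) {
  stopifnot(n_patients >= 2, n_genes >= 1,
            baseline_shape > 0, baseline_scale > 0, censor_rate >= 0)
  if (is.null(gene_cov)) gene_cov <- 0.5^abs(outer(1:n_genes, 1:n_genes, "-"))
  check_psd(gene_cov, n_genes)
  if (is.null(true_beta)) true_beta <- default_true_beta()
  structure(list(n_patients = as.integer(n_patients),
                 n_genes = as.integer(n_genes),
                 gene_cov = gene_cov,
                 gene_mean = rep_len(gene_mean, n_genes),
                 true_beta = true_beta,
                 baseline_shape = baseline_shape,
                 baseline_scale = baseline_scale,
                 censor_rate = censor_rate,
                 admin_censor_time = admin_censor_time,
                 seed = as.integer(seed)),
            class = "cohort_sim_params")
}

check_psd <- function(S, n) {
  if (!isTRUE(all.equal(dim(S), c(n, n))) || !isSymmetric(unname(S), tol = 1e-8))
    stop("gene_cov must be a symmetric ", n, "x", n, " matrix")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) stop("gene_cov is not positive semidefinite")
  invisible(TRUE)
}

# Four active predictors mirroring the scale of the study's final model:
# one nucleus-heterogeneity image feature (protective: lower mrate = more
# heterogeneity = worse prognosis) and three genes, one hazardous, two
# protective. Effects are on (approximately) unit-variance columns.
default_true_beta <- function() {
  c(area_mrate = -0.5, gene05 = 0.5, gene12 = -0.45, gene33 = -0.45)
}

#' Simulate an RFS cohort with known survival structure
#'
#' Event times follow a proportional-hazards model
#' `h(t|x) = h0(t) exp(beta' x)` with a Weibull baseline, inverted in closed
#' form: `T = scale * (-log U / exp(beta' x))^(1/shape)`. Censoring is the
#' minimum of an independent exponential draw and the administrative cap;
#' observed `time = min(T, C)`, `event = [T <= C]`.
#'
#' Image features come from real slides when `slides` (or a precomputed
#' `image_features` matrix) is supplied; otherwise they are simulated as
#' correlated Gaussians with AR(1) correlation 0.5 and unit variance under
#' the 153 standard feature names.
#'
#' @param params a [cohort_sim_params()] object.
#' @param slides optional list of `synthetic_slide` objects (one per
#'   patient); their extracted features become the image-feature matrix.
#' @param image_features optional precomputed `n_patients x 153` matrix.
#' @param feature_config config passed to [extract_slide_features()] when
#'   `slides` is given.
#' @return object of class `cohort`: list with `time`, `event`,
#'   `covariates` (data.frame), `expression` (matrix, `log(FPKM + 1)`
#'   scale), `image_features` (matrix), `linpred` (true linear predictor,
#'   kept for oracle checks) and `params`.
#' @export
generate_cohort <- function(params, slides = NULL, image_features = NULL,
                            feature_config = NULL) {
  stopifnot(inherits(params, "cohort_sim_params"))
  n <- params$n_patients
  G <- params$n_genes

  expr <- with_substream(params$seed, "expression", {
    E <- MASS::mvrnorm(n, mu = params$gene_mean, Sigma = params$gene_cov)
    colnames(E) <- sprintf("gene%02d", seq_len(G))
    pmax(E, 0)  # log(FPKM + 1) is nonnegative
  })

  covars <- with_substream(params$seed, "covariates", {
    data.frame(
      age = round(stats::rnorm(n, 60, 11)),
      bmi = round(stats::rnorm(n, 26, 4), 1),
      male = stats::rbinom(n, 1, 0.68),
      grade = sample(1:4, n, replace = TRUE, prob = c(0.24, 0.47, 0.26, 0.03)),
      ajcc_stage = sample(1:4, n, replace = TRUE,
                          prob = c(0.50, 0.25, 0.22, 0.03))
    )
  })

  if (!is.null(slides)) {
    stopifnot(length(slides) == n)
    feats <- lapply(slides, function(s)
      extract_slide_features(s$image, config = feature_config,
                             seed = s$params$seed))
    image_features <- do.call(rbind, feats)
  } else if (is.null(image_features)) {
    image_features <- with_substream(params$seed, "image-features", {
      p <- length(slide_feature_names())
      S <- 0.5^abs(outer(seq_len(p), seq_len(p), "-"))
      X <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = S)
      colnames(X) <- slide_feature_names()
      X
    })
  }
  stopifnot(nrow(image_features) == n)

  design <- cbind(as.matrix(covars), expr, image_features)
  beta <- params$true_beta
  miss <- setdiff(names(beta), colnames(design))
  if (length(miss))
    stop("true_beta names not found in simulated columns: ",
         paste(miss, collapse = ", "))
  # center the active columns so exp(lp) is around 1 at the cohort mean
  act <- design[, names(beta), drop = FALSE]
  act <- sweep(act, 2, colMeans(act))
  lp <- drop(act %*% beta)

  surv <- with_substream(params$seed, "survival", {
    U <- stats::runif(n)
    T_ev <- params$baseline_scale *
      (-log(U) / exp(lp))^(1 / params$baseline_shape)
    C <- if (params$censor_rate > 0) {
      pmin(stats::rexp(n, rate = params$censor_rate), params$admin_censor_time)
    } else rep(params$admin_censor_time, n)
    time <- pmin(T_ev, C)
    list(time = pmax(time, 1e-8), event = as.integer(T_ev <= C))
  })

  structure(list(time = surv$time, event = surv$event,
                 covariates = covars, expression = expr,
                 image_features = image_features,
                 linpred = lp, params = params),
            class = "cohort")
}

#' Write a cohort to CSV/TSV files
#'
#' Cohort table (id, time, event, covariates) as CSV; expression and image
#' features as TSV with patient ids in the first column.
#'
#' @param cohort a `cohort`.
#' @param dir output directory.
#' @param stem file stem.
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, stem = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- sprintf("P%04d", seq_along(cohort$time))
  p1 <- file.path(dir, paste0(stem, ".csv"))
  utils::write.csv(cbind(data.frame(id = id, time = cohort$time,
                                    event = cohort$event), cohort$covariates),
                   p1, row.names = FALSE)
  p2 <- file.path(dir, paste0(stem, "_expression.tsv"))
  utils::write.table(data.frame(id = id, cohort$expression,
                                check.names = FALSE),
                     p2, sep = "\t", row.names = FALSE, quote = FALSE)
  p3 <- file.path(dir, paste0(stem, "_features.tsv"))
  utils::write.table(data.frame(id = id, cohort$image_features,
                                check.names = FALSE),
                     p3, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(cohort = p1, expression = p2, features = p3))
}

#' Domain design matrices of a cohort
#'
#' @param cohort a `cohort`.
#' @param domains character subset of `c("clin", "image", "genes")`.
#' @return named list of numeric matrices with patients in rows.
#' @export
cohort_domains <- function(cohort, domains = c("clin", "image", "genes")) {
  all <- list(clin = as.matrix(cohort$covariates),
              image = cohort$image_features,
              genes = cohort$expression)
  all[match.arg(domains, names(all), several.ok = TRUE)]
}
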