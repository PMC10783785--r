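#' Median split of risk scores into lower/higher-risk groups
#'
#' The sample median (midpoint of order statistics for even n) divides the
#' cohort; scores at or below the median are "lower", above it "higher".
#' With 231 distinct scores this yields 116 lower / 115 higher.
#'
#' @param scores numeric vector, length >= 2.
#' @return factor with levels `c("lower", "higher")`.
#' @export
median_split <- function(scores) {
  stopifnot(length(scores) >= 2)
  med <- stats::median(scores)
  factor(ifelse(scores <= med, "lower", "higher"),
         levels = c("lower", "higher"))
}

#' Kaplan-Meier estimate with median survival and 95% CI
#'
#' Product-limit estimator with Greenwood variance and log(-log)
#' confidence bands. The median is the first time the survival curve drops
#' to 0.5 or below; its confidence limits invert the pointwise bands
#' (first times the upper/lower band drops to 0.5 or below). A curve never
#' reaching 0.5 has `median = NA` ("not reached").
#'
#' @param time,event survival outcome.
#' @return object of class `km_fit`: list with `time`, `surv`, `lower`,
#'   `upper` (step function over event times), `median`, `median_lcl`,
#'   `median_ucl`, `n`, `n_events`.
#' @export
kaplan_meier <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log")
  first_at_or_below <- function(s, tt, level = 0.5) {
    i <- which(!is.na(s) & s <= level + 1e-12)
    if (length(i)) tt[min(i)] else NA_real_
  }
  structure(list(time = fit$time, surv = fit$surv,
                 lower = fit$lower, upper = fit$upper,
                 median = first_at_or_below(fit$surv, fit$time),
                 # band inversion: the lower band crosses 1/2 first
                 median_lcl = first_at_or_below(fit$lower, fit$time),
                 median_ucl = first_at_or_below(fit$upper, fit$time),
                 n = length(time), n_events = sum(event)),
            class = "km_fit")
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank test (hypergeometric variance).
#'
#' @param time,event survival outcome.
#' @param groups factor or vector with exactly two distinct values.
#' @return list with `chisq`, `df`, `p_value`.
#' @export
logrank_test <- function(time, event, groups) {
  g <- droplevels(as.factor(groups))
  if (nlevels(g) != 2) stop("log-rank test requires exactly two groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  list(chisq = sd$chisq, df = 1L,
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Hazard ratio per unit of a continuous risk score
#'
#' Univariate Cox model of the outcome on the score; returns
#' `HR = exp(beta)` with the Wald 95% CI and p-value.
#'
#' @param score numeric risk score with nonzero variance.
#' @param time,event survival outcome.
#' @return list with `hr`, `lcl`, `ucl`, `beta`, `se`, `p_value`.
#' @export
score_hazard_ratio <- function(score, time, event) {
  if (stats::sd(score) == 0) stop("score has zero variance")
  fit <- survival::coxph(survival::Surv(time, event) ~ score, ties = "efron")
  if (!is.finite(fit$coefficients))
    stop("Cox model did not converge")
  b <- unname(fit$coefficients)
  se <- sqrt(unname(fit$var[1, 1]))
  list(hr = exp(b), lcl = exp(b - 1.96 * se), ucl = exp(b + 1.96 * se),
       beta = b, se = se,
       p_value = 2 * stats::pnorm(-abs(b / se)))
}

#' Full risk stratification of a cohort by a continuous score
#'
#' Median split, per-group Kaplan-Meier with median RFS and 95% CI,
#' two-group log-rank test, and the per-unit hazard ratio of the
#' continuous score.
#'
#' @param scores per-patient risk scores.
#' @param time,event survival outcome.
#' @return object of class `stratification_result`.
#' @export
stratify_cohort <- function(scores, time, event) {
  grp <- median_split(scores)
  km <- lapply(split(seq_along(time), grp), function(i)
    kaplan_meier(time[i], event[i]))
  structure(list(groups = grp,
                 n_lower = sum(grp == "lower"),
                 n_higher = sum(grp == "higher"),
                 km = km,
                 logrank = logrank_test(time, event, grp),
                 hr = score_hazard_ratio(scores, time, event)),
            class = "stratification_result")
}

#' Plot Kaplan-Meier curves of a stratification with 95% bands
#'
#' @param x a `stratification_result`.
#' @param ... passed to [plot()].
#' @return invisibly, `x`.
#' @export
plot.stratification_result <- function(x, ...) {
  cols <- c(lower = "#2166ac", higher = "#b2182b")
  xmax <- max(unlist(lapply(x$km, `[[`, "time")))
  plot(NA, xlim = c(0, xmax), ylim = c(0, 1),
       xlab = "Days", ylab = "Recurrence-free survival", ...)
  for (g in names(x$km)) {
    k <- x$km[[g]]
    tt <- c(0, k$time); ss <- c(1, k$surv)
    lo <- c(1, ifelse(is.na(k$lower), 1, k$lower))
    up <- c(1, ifelse(is.na(k$upper), 1, k$upper))
    graphics::polygon(c(rep(tt, each = 2)[-1], rev(rep(tt, each = 2)[-1])),
                      c(rep(lo, each = 2)[-2 * length(lo)],
                        rev(rep(up, each = 2)[-2 * length(up)])),
                      col = grDevices::adjustcolor(cols[g], 0.2), border = NA)
    graphics::lines(stats::stepfun(k$time, ss), do.points = FALSE,
                    col = cols[g], lwd = 2)
  }
  graphics::legend("topright", legend = names(x$km), col = cols[names(x$km)],
                   lwd = 2, bty = "n")
  invisible(x)
}
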