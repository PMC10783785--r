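#' Harrell's concordance index
#'
#' Over all comparable pairs — pairs where the subject with the shorter
#' observed time had an event (a censored subject tied in time with an
#' event counts as outliving it) — a pair is concordant (1) when the
#' earlier-failing subject has the higher score, tied (0.5) when scores are
#' equal, discordant (0) otherwise. Returns the concordant fraction: 0.5 is
#' random, 1 perfect.
#'
#' @param scores numeric risk scores (higher = higher predicted risk).
#' @param time,event survival outcome.
#' @return C-index in `[0, 1]`; errors when no pair is comparable.
#' @export
harrell_cindex <- function(scores, time, event) {
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n, n >= 2)
  dt <- outer(time, time, "<")
  tie_t <- outer(time, time, "==")
  ei <- matrix(event == 1, n, n)
  ej_cens <- matrix(event == 0, n, n, byrow = TRUE)
  comparable <- (dt & ei) | (tie_t & ei & ej_cens)
  if (!any(comparable)) stop("C-index undefined: no comparable pairs")
  ds <- outer(scores, scores, "-")
  num <- sum((ds > 0) * comparable) + 0.5 * sum((ds == 0) * comparable)
  num / sum(comparable)
}

#' IPCW time-dependent AUC (cumulative/dynamic)
#'
#' At each grid time `t`, cases are test subjects with an observed event by
#' `t` and controls those still at risk beyond `t`; the AUC is the
#' weighted probability that a case outscores a control (ties count 0.5),
#' with inverse-probability-of-censoring weights `1/G(T_i-)` for cases and
#' `1/G(t)` for controls, `G` the Kaplan-Meier estimate of the censoring
#' distribution fitted on the *training* outcome. The summary "mean
#' time-dependent AUC" is the unweighted mean over the grid.
#'
#' @param scores numeric risk scores on the test set.
#' @param train_time,train_event training outcome (for the censoring KM).
#' @param test_time,test_event test outcome.
#' @param time_grid evaluation times; default: the event-time quantiles at
#'   probabilities 0.1 to 0.8 in steps of 0.1 (deciles of observed test
#'   event times inside the central follow-up range).
#' @return list with `time_grid`, `auc` (vector), `mean_auc`.
#' @export
time_dependent_auc <- function(scores, train_time, train_event,
                               test_time, test_event, time_grid = NULL) {
  stopifnot(length(scores) == length(test_time))
  if (is.null(time_grid)) {
    ev <- test_time[test_event == 1]
    if (!length(ev)) stop("no events in test data")
    time_grid <- unique(stats::quantile(ev, probs = seq(0.1, 0.8, by = 0.1),
                                        names = FALSE, type = 7))
  }
  if (any(time_grid > max(test_time)))
    stop("time grid extends beyond the last observed test time")
  Gfit <- survival::survfit(survival::Surv(train_time, 1 - train_event) ~ 1)
  Gfun <- stats::stepfun(Gfit$time, c(1, Gfit$surv))
  Gminus <- function(t) Gfun(t - 1e-9)
  auc <- vapply(time_grid, function(t) {
    case <- test_time <= t & test_event == 1
    ctrl <- test_time > t
    if (!any(case) || !any(ctrl)) return(NA_real_)
    wc <- 1 / pmax(Gminus(test_time[case]), 1e-8)
    wk <- rep(1 / pmax(Gfun(t), 1e-8), sum(ctrl))
    ds <- outer(scores[case], scores[ctrl], "-")
    W <- outer(wc, wk)
    sum(W * ((ds > 0) + 0.5 * (ds == 0))) / sum(W)
  }, numeric(1))
  list(time_grid = time_grid, auc = auc,
       mean_auc = mean(auc, na.rm = TRUE))
}
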