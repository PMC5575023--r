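# Time-dependent (cumulative/dynamic) ROC for censored outcomes: the
# Kaplan-Meier-based estimator of Heagerty, Lumley & Pepe, with the known
# non-monotonicity repaired by a cumulative maximum over the ROC curve.

# Product-limit survival at a single time point (Breslow-free, exact).
.km_at <- function(time, event, t) {
  if (!length(time)) return(1)
  dt <- sort(unique(time[event == 1 & time <= t]))
  if (!length(dt)) return(1)
  s <- 1
  for (ti in dt) s <- s * (1 - sum(time == ti & event == 1) / sum(time >= ti))
  s
}

#' Time-dependent ROC curve and AUC under censoring
#'
#' Estimates the cumulative/dynamic ROC at horizon `t` for a baseline marker
#' X: cases are subjects with an event by `t` (`D(t) = 1`), controls those
#' event-free at `t`. Sensitivity and specificity are estimated with the
#' Kaplan-Meier-based plug-in
#' \deqn{\widehat{\mathrm{sens}}(c,t) = \frac{\{1 - \hat S(t \mid X > c)\}
#'   \hat P(X > c)}{1 - \hat S(t)}, \qquad
#'   \widehat{\mathrm{spec}}(c,t) = \frac{\hat S(t \mid X \le c)
#'   \hat P(X \le c)}{\hat S(t)}}
#' with conditional survival estimated by the product-limit method within
#' each marker stratum. The resulting curve need not be monotone; the ROC is
#' repaired by a cumulative maximum over thresholds before trapezoidal
#' integration, and sensitivities/specificities are clamped to \eqn{[0,1]}.
#' In the absence of censoring the estimator reduces exactly to the
#' empirical ROC of the binary status `D(t)` (and the AUC to the
#' Mann-Whitney statistic). If all marker values are tied the AUC is 0.5 by
#' convention.
#'
#' @param marker Numeric marker values (higher = higher predicted risk).
#' @param time,event Survival outcome.
#' @param t Horizon; at least one event by `t` and one subject observed past
#'   `t` are required.
#' @return An object of class `"td_roc"`: `t`, `thresholds`, raw
#'   `sensitivity`/`specificity`, the repaired `fpr`/`tpr` curve and `auc`.
#' @export
td_roc <- function(marker, time, event, t) {
  n <- length(marker)
  if (length(time) != n || length(event) != n) stop("length mismatch")
  if (!is.finite(t)) stop("`t` must be finite")
  if (!any(time <= t & event == 1)) stop("no events observed before the horizon t")
  if (!any(time > t)) stop("no subjects observed past the horizon t")
  cs <- sort(unique(marker))
  if (length(cs) == 1L) {
    return(structure(list(t = t, thresholds = cs, sensitivity = NA_real_,
                          specificity = NA_real_, fpr = c(0, 1), tpr = c(0, 1),
                          auc = 0.5, n = n), class = "td_roc"))
  }
  st <- .km_at(time, event, t)
  sens <- spec <- numeric(length(cs))
  for (i in seq_along(cs)) {
    hi <- marker > cs[i]
    p1 <- mean(hi)
    if (p1 > 0) {
      s1 <- .km_at(time[hi], event[hi], t)
      sens[i] <- (1 - s1) * p1 / (1 - st)
    }
    if (p1 < 1) {
      s0 <- .km_at(time[!hi], event[!hi], t)
      spec[i] <- s0 * (1 - p1) / st
    }
  }
  sens <- pmin(pmax(sens, 0), 1)
  spec <- pmin(pmax(spec, 0), 1)
  # walk the thresholds from +Inf (0,0) down to -Inf (1,1); cummax on both
  # coordinates repairs the estimator's occasional non-monotonicity
  fpr <- cummax(c(0, rev(1 - spec), 1))
  tpr <- cummax(c(0, rev(sens), 1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(t = t, thresholds = cs, sensitivity = sens,
                 specificity = spec, fpr = fpr, tpr = tpr, auc = auc, n = n),
            class = "td_roc")
}

#' @export
print.td_roc <- function(x, ...) {
  cat(sprintf("time-dependent ROC at t = %g: AUC = %.4f (n = %d)\n",
              x$t, x$auc, x$n))
  invisible(x)
}

#' @export
plot.td_roc <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC(t = %g), AUC = %.3f", x$t, x$auc), ...)
  abline(0, 1, lty = 3, col = "grey")
  invisible(x)
}

#' Cross-validated time-dependent AUC
#'
#' Builds out-of-fold marker values with `marker_builder` over
#' event-stratified folds, pools them and evaluates a single [td_roc()] on
#' the pooled predictions.
#'
#' @param marker_builder `function(x_train, time_train, event_train, x_test)`
#'   returning one marker value per row of `x_test`. A builder that ignores
#'   its training arguments reproduces the apparent (in-sample) AUC.
#' @param x Samples x proteins matrix.
#' @param time,event Survival outcome.
#' @param t Horizon passed to [td_roc()].
#' @param nfolds Number of folds (default 10).
#' @param seed Optional integer seed for the fold assignment.
#' @return The pooled out-of-fold AUC (numeric scalar), with the full
#'   `"td_roc"` object as attribute `"roc"`.
#' @export
cv_auc <- function(marker_builder, x, time, event, t, nfolds = 10,
                   seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (!is.null(seed)) set.seed(seed)
  for (attempt in seq_len(20L)) {
    fold <- .stratified_folds(event, nfolds)
    scores <- rep(NA_real_, n)
    ok <- TRUE
    for (k in seq_len(nfolds)) {
      te <- fold == k
      if (sum(event[!te]) < 1) {
        ok <- FALSE
        break
      }
      sc <- tryCatch(
        marker_builder(x[!te, , drop = FALSE], time[!te], event[!te],
                       x[te, , drop = FALSE]),
        error = function(e) NULL
      )
      if (is.null(sc) || length(sc) != sum(te) || anyNA(sc)) {
        ok <- FALSE
        break
      }
      scores[te] <- sc
    }
    if (ok) {
      roc <- td_roc(scores, time, event, t)
      return(structure(roc$auc, roc = roc, fold = fold))
    }
  }
  stop("cross-validation failed in every of 20 fold draws")
}
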