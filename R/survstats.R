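# Classical survival machinery used for validation, delegating the
# estimation to the survival package (Breslow ties everywhere, matching the
# SOGL solver) behind small typed wrappers.

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function; censored subjects leave
#' the risk set after their time, and at tied event/censoring times the
#' events are counted first (the standard convention of
#' [survival::survfit()]).
#'
#' @param time,event Survival outcome (`time >= 0`).
#' @return An object of class `"km_curve"` with the drop times
#'   (`event_times`), the survival probabilities after each drop
#'   (`survival`), and the `at_risk` / `n_events` counts. With no events the
#'   curve is identically 1 and `event_times` is empty.
#' @export
km_estimate <- function(time, event) {
  if (any(time < 0)) stop("negative survival times")
  if (!length(time)) stop("empty survival data")
  fit <- survfit(Surv(time, as.integer(event != 0)) ~ 1)
  keep <- fit$n.event > 0
  structure(list(event_times = fit$time[keep], survival = fit$surv[keep],
                 at_risk = fit$n.risk[keep], n_events = fit$n.event[keep],
                 n = length(time)), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d event times\n",
              x$n, length(x$event_times)))
  if (length(x$event_times)) {
    print(data.frame(time = x$event_times, at_risk = x$at_risk,
                     events = x$n_events, survival = x$survival),
          digits = 4, row.names = FALSE)
  } else {
    cat("no events: S(t) = 1 everywhere\n")
  }
  invisible(x)
}

#' Survival probability from a Kaplan-Meier curve
#'
#' @param km A `"km_curve"`.
#' @param t Time points.
#' @return \eqn{\hat S(t)} (right-continuous step function; 1 before the
#'   first event).
#' @export
km_survival <- function(km, t) {
  stopifnot(inherits(km, "km_curve"))
  vapply(t, function(ti) {
    i <- sum(km$event_times <= ti)
    if (i == 0) 1 else km$survival[i]
  }, numeric(1))
}

#' Log-rank test across groups
#'
#' K-sample log-rank statistic with the hypergeometric variance and a
#' chi-square reference on k - 1 degrees of freedom.
#'
#' @param time,event Survival outcome.
#' @param group Group labels (>= 2 non-empty groups).
#' @return An object of class `"logrank_test"` with `chi_square`, `df`,
#'   `p_value` and the per-group observed/expected table.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2) stop("log-rank needs at least two groups")
  sd <- survdiff(Surv(time, as.integer(event != 0)) ~ group)
  df <- length(sd$n) - 1L
  structure(list(chi_square = unname(sd$chisq), df = df,
                 p_value = pchisq(sd$chisq, df, lower.tail = FALSE),
                 observed = sd$obs, expected = sd$exp),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("log-rank test: chi-square = %.4f on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' Cox proportional hazards fit with a tidy coefficient table
#'
#' Wraps [survival::coxph()] with the Breslow tie convention. Hazard ratios
#' and 95% Wald confidence intervals come from the observed information; a
#' convergence warning from the underlying Newton-Raphson (e.g. separation)
#' is promoted to an error.
#'
#' @param time,event Survival outcome.
#' @param covariates Data frame or matrix of covariates (no constant
#'   columns; at least as many events as covariates).
#' @param names Optional covariate display names.
#' @return An object of class `"cox_fit"`: a data frame `table` with
#'   columns `term`, `coef`, `hr`, `ci_low`, `ci_high`, `p_value`, plus
#'   `converged`, `n`, `n_events` and the underlying fit.
#' @export
cox_fit <- function(time, event, covariates, names = NULL) {
  covariates <- as.data.frame(covariates)
  if (!ncol(covariates)) stop("no covariates")
  if (is.null(names)) names <- colnames(covariates)
  cv <- vapply(covariates, function(z) var(as.numeric(z)), numeric(1))
  if (any(cv == 0)) stop("constant covariate: ", names[which(cv == 0)[1]])
  ne <- sum(event != 0)
  if (ne < ncol(covariates)) {
    stop("fewer events than covariates; the fit is unidentified")
  }
  df <- covariates
  colnames(df) <- make.names(colnames(df), unique = TRUE)
  fit <- withCallingHandlers(
    coxph(Surv(time, as.integer(event != 0)) ~ ., data = df,
          ties = "breslow", control = coxph.control(iter.max = 50)),
    warning = function(w) {
      if (grepl("converge|infinite|singular", conditionMessage(w))) {
        stop("Cox fit did not converge: ", conditionMessage(w))
      }
      invokeRestart("muffleWarning")
    }
  )
  s <- summary(fit)$coefficients
  tab <- data.frame(
    term = names,
    coef = s[, "coef"],
    hr = exp(s[, "coef"]),
    ci_low = exp(s[, "coef"] - 1.959963984540054 * s[, "se(coef)"]),
    ci_high = exp(s[, "coef"] + 1.959963984540054 * s[, "se(coef)"]),
    p_value = s[, "Pr(>|z|)"],
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(table = tab, converged = TRUE, n = length(time),
                 n_events = ne, fit = fit), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional hazards fit: n = %d, events = %d\n",
              x$n, x$n_events))
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Univariate Cox screen over candidate factors
#'
#' Fits each factor marginally and retains those with Wald p below the
#' threshold, the usual gate before a multivariable model.
#'
#' @param time,event Survival outcome.
#' @param factors Data frame of candidate factors.
#' @param threshold Wald p-value threshold (default 0.05).
#' @return List with the per-factor `table` (term, coef, hr, ci, p) and the
#'   `selected` factor names.
#' @export
univariate_screen <- function(time, event, factors, threshold = 0.05) {
  factors <- as.data.frame(factors)
  rows <- lapply(seq_along(factors), function(j) {
    f <- tryCatch(cox_fit(time, event, factors[, j, drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(f)) {
      return(data.frame(term = names(factors)[j], coef = NA, hr = NA,
                        ci_low = NA, ci_high = NA, p_value = NA))
    }
    f$table
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       selected = tab$term[!is.na(tab$p_value) & tab$p_value < threshold])
}

#' Tertile-style risk grouping at the quartile cutoffs
#'
#' Splits scores into `low` (score <= 25th percentile), `high` (score >
#' 75th percentile) and `medium` (otherwise). Percentiles use linear
#' interpolation of order statistics (R's default type-7 quantile), so group
#' sizes are fully determined by that rule.
#'
#' @param scores Numeric vector (`n >= 4`, not all equal).
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
risk_groups <- function(scores) {
  if (length(scores) < 4) stop("need at least 4 scores to form risk groups")
  if (length(unique(scores)) == 1L) {
    stop("all scores are equal: risk groups are degenerate")
  }
  q <- quantile(scores, c(0.25, 0.75), type = 7, names = FALSE)
  factor(ifelse(scores <= q[1], "low", ifelse(scores > q[2], "high", "medium")),
         levels = c("low", "medium", "high"))
}
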