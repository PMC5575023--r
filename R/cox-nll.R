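# Cox partial-likelihood machinery shared by the SOGL solver and the
# classical fits. Breslow convention for tied failure times throughout.

# Precompute the sort order and tie-block bookkeeping for repeated
# likelihood/gradient evaluations on the same outcome.
.cox_prep <- function(time, event) {
  if (length(time) != length(event)) {
    stop("`time` and `event` must have the same length")
  }
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("survival times must be finite and non-negative")
  }
  event <- as.integer(event != 0)
  ord <- order(time)
  ts <- time[ord]
  ev <- event[ord]
  u <- unique(ts)                       # sorted
  bid <- match(ts, u)
  first <- match(u, ts)
  len <- tabulate(bid)
  list(
    n = length(ts), ord = ord, time = ts, event = ev,
    block_first = first[bid],
    block_last = first[bid] + len[bid] - 1L,
    n_events = sum(ev)
  )
}

# Scaled negative log partial likelihood given the linear predictor eta
# (original sample order). Risk sets are {j : t_j >= t_i}; the max-shift
# keeps exp() finite for large |eta|.
.cox_nll_eta <- function(eta, prep) {
  es <- eta[prep$ord]
  m <- max(es)
  w <- exp(es - m)
  cum <- rev(cumsum(rev(w)))
  d <- prep$event == 1L
  logden <- log(cum[prep$block_first[d]]) + m
  (sum(logden) - sum(es[d])) / prep$n
}

# d(nll)/d(eta), original sample order. For subject j the weight is
# exp(eta_j) * sum_{i in D : t_i <= t_j} 1/denom_i - event_j, all over n.
.cox_grad_eta <- function(eta, prep) {
  es <- eta[prep$ord]
  m <- max(es)
  w <- exp(es - m)
  cum <- rev(cumsum(rev(w)))
  r <- ifelse(prep$event == 1L, 1 / cum[prep$block_first], 0)
  a <- cumsum(r)[prep$block_last]
  gs <- w * a - prep$event
  g <- numeric(prep$n)
  g[prep$ord] <- gs
  g / prep$n
}

#' Negative log Cox partial likelihood
#'
#' Evaluates the scaled negative log partial likelihood
#' \deqn{\frac{1}{n} \sum_{i \in D} \left[\log \sum_{j \in R_i}
#'   \exp(x_j^\top v) - x_i^\top v\right]}
#' where \eqn{D} is the set of failures and \eqn{R_i = \{j : t_j \ge t_i\}}
#' the risk set at the i-th failure time. Tied failure times use the Breslow
#' convention (tied failures share one denominator over the common risk set).
#'
#' This is the smooth loss term of the sparse overlapping group lasso Cox
#' objective; it is exposed so the solver can be checked against independent
#' implementations.
#'
#' @param v Numeric coefficient vector, length `ncol(x)`.
#' @param x Numeric design matrix, samples in rows.
#' @param time Non-negative follow-up times.
#' @param event Event indicator (1 = failure, 0 = censored).
#' @return A single non-negative number.
#' @examples
#' x <- matrix(rnorm(12), 3, 4)
#' cox_nll(rep(0, 4), x, time = 1:3, event = c(1, 1, 1))  # log(6)/3
#' @export
cox_nll <- function(v, x, time, event) {
  x <- as.matrix(x)
  if (length(v) != ncol(x)) stop("length(v) must equal ncol(x)")
  if (nrow(x) != length(time)) stop("nrow(x) must equal length(time)")
  prep <- .cox_prep(time, event)
  if (prep$n_events == 0L) stop("no events: the partial likelihood is undefined")
  .cox_nll_eta(drop(x %*% v), prep)
}
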