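#' Smallest penalty level with an all-zero solution
#'
#' Computes the entry point of the regularization path from the null-model
#' gradient: zero solves the penalized problem iff, for every group g,
#' \eqn{\|S(\nabla_g, \lambda\alpha)\|_2 \le \lambda (1-\alpha) d_g}, where
#' \eqn{S} is elementwise soft-thresholding of the gradient of the (scaled)
#' negative log partial likelihood at v = 0. Each group's critical level is
#' found by bisection (the left side decreases in lambda, the right side
#' increases); the path starts at the maximum over groups.
#'
#' @inheritParams cox_nll
#' @param xtilde Duplicated design matrix (see [expand_design()]).
#' @param alpha Sparse/group mixing weight in \eqn{[0,1]}.
#' @param groups,d_g Group index list and weights from [expand_design()].
#' @return A positive scalar lambda at which the fitted solution is exactly
#'   zero (and below which, up to bisection tolerance, it is not).
#' @export
lambda_max <- function(xtilde, time, event, alpha, groups, d_g) {
  xtilde <- as.matrix(xtilde)
  sds <- apply(xtilde, 2, sd)
  if (any(sds == 0)) {
    stop("constant columns in the design: lambda_max is undefined")
  }
  prep <- .cox_prep(time, event)
  if (prep$n_events == 0L) stop("no events: cannot compute lambda_max")
  g0 <- drop(crossprod(xtilde, .cox_grad_eta(rep(0, prep$n), prep)))
  if (alpha >= 1) return(max(abs(g0)) * (1 + 1e-8))
  crit <- function(gv, dg) {
    if (alpha == 0) return(sqrt(sum(gv^2)) / dg)
    lo <- 0
    hi <- sqrt(sum(gv^2)) / ((1 - alpha) * dg)
    if (hi == 0) return(0)
    for (i in 1:100) {
      mid <- (lo + hi) / 2
      s <- pmax(abs(gv) - mid * alpha, 0)
      if (sqrt(sum(s^2)) <= mid * (1 - alpha) * dg) hi <- mid else lo <- mid
    }
    hi  # upper bracket: the zero solution is guaranteed at this level
  }
  lm <- max(vapply(seq_along(groups),
                   function(k) crit(g0[groups[[k]]], d_g[k]), numeric(1)))
  lm * (1 + 1e-8)  # margin over the bisection bracket: zero fit guaranteed
}
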