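#' Proximal operator of the sparse group lasso penalty
#'
#' Computes \eqn{\mathrm{argmin}_v \; \frac{1}{2}\|v - z\|_2^2 +
#' s\,\lambda\,[\alpha \|v\|_1 + (1-\alpha) \sum_g d_g \|v^g\|_2]} for groups
#' that partition the coordinates of `z` (on the duplicated design every
#' latent copy belongs to exactly one group, so the penalty is separable and
#' the solution is closed-form): elementwise soft-thresholding at
#' \eqn{s\lambda\alpha} followed by groupwise shrinkage by
#' \eqn{\max(0, 1 - s\lambda(1-\alpha) d_g / \|\cdot\|_2)}. Groups whose
#' post-threshold norm does not exceed \eqn{s\lambda(1-\alpha) d_g} are set
#' exactly to zero.
#'
#' @param z Numeric vector.
#' @param groups List of integer index vectors partitioning `seq_along(z)`.
#' @param step Positive step size \eqn{s}.
#' @param lambda Non-negative penalty level.
#' @param alpha Mixing weight in \eqn{[0,1]}; 1 is the lasso limit, 0 the
#'   pure group lasso.
#' @param d_g Positive per-group weights, one per element of `groups`.
#' @return Numeric vector of the same length as `z`.
#' @examples
#' prox_sparse_group(c(3, 4), list(1:2), step = 1, lambda = 1,
#'                   alpha = 0.5, d_g = 1)
#' @export
prox_sparse_group <- function(z, groups, step, lambda, alpha, d_g) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0) {
    stop("`step` must be a positive scalar")
  }
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]")
  if (length(d_g) != length(groups)) {
    stop("`d_g` must supply one weight per group")
  }
  thr <- step * lambda * alpha
  v <- sign(z) * pmax(abs(z) - thr, 0)
  fac <- step * lambda * (1 - alpha)
  if (fac > 0) {
    for (k in seq_along(groups)) {
      g <- groups[[k]]
      nrm <- sqrt(sum(v[g]^2))
      v[g] <- if (nrm <= fac * d_g[k]) 0 else v[g] * (1 - fac * d_g[k] / nrm)
    }
  }
  v
}

# Penalty value lambda * (alpha * l1 + (1 - alpha) * sum_g d_g ||v_g||_2).
.sogl_penalty <- function(v, groups, d_g, alpha, lambda) {
  l2 <- 0
  for (k in seq_along(groups)) l2 <- l2 + d_g[k] * sqrt(sum(v[groups[[k]]]^2))
  lambda * (alpha * sum(abs(v)) + (1 - alpha) * l2)
}
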