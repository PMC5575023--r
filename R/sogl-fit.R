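# Accelerated proximal gradient (monotone FISTA with backtracking and
# adaptive restart) for the sparse overlapping group lasso Cox objective on
# the duplicated design, plus the path / cross-validation drivers and the
# user-facing fitting function.

.sogl_solve <- function(xt, prep, groups, d_g, lambda, alpha, v0,
                        step = 1, tol = 1e-8, maxit = 10000L) {
  f <- function(v) .cox_nll_eta(drop(xt %*% v), prep)
  gr <- function(v) drop(crossprod(xt, .cox_grad_eta(drop(xt %*% v), prep)))
  x <- v0
  fx <- f(x)
  obj <- fx + .sogl_penalty(x, groups, d_g, alpha, lambda)
  y <- x
  tk <- 1
  for (it in seq_len(maxit)) {
    fy <- f(y)
    gy <- gr(y)
    repeat {
      z <- prox_sparse_group(y - step * gy, groups, step, lambda, alpha, d_g)
      dz <- z - y
      fz <- f(z)
      if (fz <= fy + sum(gy * dz) + sum(dz^2) / (2 * step) + 1e-12) break
      step <- step / 2
      if (step < 1e-16) stop("backtracking line search failed (step underflow)")
    }
    objz <- fz + .sogl_penalty(z, groups, d_g, alpha, lambda)
    t1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
    if (objz <= obj) {
      # monotone step: accept the prox point, keep momentum on it
      y <- z + ((tk - 1) / t1) * (z - x)
      relchg <- (obj - objz) / max(1, abs(objz))
      x <- z
      obj <- objz
      tk <- t1
      if (relchg < tol && it > 1L) {
        return(list(v = x, objective = obj, iterations = it,
                    step = step, converged = TRUE))
      }
    } else {
      # objective would increase: restart the momentum from the best point
      y <- x
      tk <- 1
    }
    step <- min(step * 1.1, 1e6)
  }
  gfin <- gr(x)
  stop(sprintf(
    "SOGL solver did not converge at lambda = %.6g (%d iterations, gradient norm %.3g)",
    lambda, maxit, sqrt(sum(gfin^2))
  ))
}

.sogl_fit_path <- function(xt, prep, groups, d_g, alpha, lambdas,
                           tol = 1e-8, maxit = 10000L) {
  p <- ncol(xt)
  v_path <- matrix(0, p, length(lambdas))
  obj <- numeric(length(lambdas))
  v <- numeric(p)
  step <- 1
  for (i in seq_along(lambdas)) {   # warm starts down the path
    sol <- .sogl_solve(xt, prep, groups, d_g, lambdas[i], alpha, v,
                       step = step, tol = tol, maxit = maxit)
    v <- sol$v
    step <- sol$step
    v_path[, i] <- v
    obj[i] <- sol$objective
  }
  list(v = v_path, objective = obj)
}

# Folds stratified by event status; returns an integer fold label per sample.
.stratified_folds <- function(event, k) {
  fold <- integer(length(event))
  for (lev in unique(event)) {
    idx <- which(event == lev)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# Verweij & Van Houwelingen cross-validated partial likelihood: for each
# held-out fold the contribution is the full-data (unscaled) nll at the
# fold-trained coefficients minus the training-only nll.
.sogl_cv <- function(xs, time, event, groups, d_g, alpha, lambdas,
                     nfolds, seed = NULL, tol = 1e-8, maxit = 10000L) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(time)
  prep_full <- .cox_prep(time, event)
  fold <- NULL
  for (attempt in seq_len(20L)) {
    cand <- .stratified_folds(event, nfolds)
    ok <- all(vapply(seq_len(nfolds), function(k) {
      sum(event[cand != k]) >= 1
    }, logical(1)))
    if (ok) {
      fold <- cand
      break
    }
  }
  if (is.null(fold)) stop("could not build folds with events in every training split")
  loss <- matrix(NA_real_, nfolds, length(lambdas))
  for (k in seq_len(nfolds)) {
    tr <- fold != k
    prep_tr <- .cox_prep(time[tr], event[tr])
    pk <- .sogl_fit_path(xs[tr, , drop = FALSE], prep_tr, groups, d_g,
                         alpha, lambdas, tol = tol, maxit = maxit)
    for (i in seq_along(lambdas)) {
      v <- pk$v[, i]
      l_full <- .cox_nll_eta(drop(xs %*% v), prep_full) * n
      l_tr <- .cox_nll_eta(drop(xs[tr, , drop = FALSE] %*% v), prep_tr) * sum(tr)
      loss[k, i] <- l_full - l_tr
    }
  }
  cvm <- colMeans(loss)
  idx <- which.min(cvm)  # lambdas decrease, so ties resolve to the larger lambda
  list(fold = fold, loss = loss, cvm = cvm,
       lambda_min = lambdas[idx], index = idx)
}

#' Fit a sparse overlapping group lasso Cox model over pathways
#'
#' Fits the penalized Cox proportional hazards model
#' \deqn{\min_{\tilde v} \; \frac{1}{n}\sum_{i \in D}\Big[\log\!\!\sum_{j \in
#'   R_i}\exp(\tilde X_j \tilde v) - \tilde X_i \tilde v\Big] +
#'   \lambda\Big[(1-\alpha)\sum_{g} d_g \|\tilde v^g\|_2 +
#'   \alpha\|\tilde v\|_1\Big]}
#' where \eqn{\tilde X} is the duplicated design produced by
#' [expand_design()] (one latent copy of every protein per pathway it belongs
#' to). The model is solved by monotone accelerated proximal gradient descent
#' with backtracking along a geometric path of `nlambda` penalty levels from
#' `lambda_max` (all-zero solution) down to `lambda.min.ratio * lambda_max`,
#' with warm starts. The penalty level is then chosen by `nfolds`-fold
#' cross-validation of the Verweij-Van Houwelingen partial-likelihood
#' contrast, with folds stratified by event status.
#'
#' Duplicated columns are centred and scaled to unit variance before fitting;
#' all reported coefficients are on that standardized scale. Collapsed
#' protein coefficients are the sums of the protein's latent copies,
#' \eqn{\hat\beta_j = \sum_{g \ni j} \hat{\tilde v}^g_j}. A negative
#' collapsed coefficient means higher expression is associated with longer
#' survival.
#'
#' @param x Numeric matrix of (preprocessed) protein abundances, samples in
#'   rows, proteins in columns; column names are protein identifiers.
#' @param time,event Follow-up time and event indicator (1 = failure).
#' @param pathways [pathway_collection] or named list of protein-identifier
#'   vectors defining the (possibly overlapping) groups.
#' @param alpha Mixing weight between the lasso (`alpha = 1`) and group
#'   lasso (`alpha = 0`) penalties. The default 0.05 favours strong
#'   group-wise sparsity with a little within-group selection.
#' @param nlambda Number of penalty levels on the path (default 20).
#' @param lambda.min.ratio Smallest penalty as a fraction of `lambda_max`
#'   (default 0.1).
#' @param group_weight Group weight rule, `"sqrt_size"` (default) or
#'   `"size"`; see [expand_design()].
#' @param nfolds Number of cross-validation folds (default 10); set to 0 or
#'   1 to skip cross-validation.
#' @param seed Optional integer seed controlling the fold assignment.
#' @param tol Relative objective-change convergence tolerance (default 1e-8).
#' @param maxit Maximum proximal-gradient iterations per penalty level.
#' @param keep_design Keep the standardized duplicated design in the returned
#'   object (needed by [pathway_score()]; default `TRUE`).
#' @return An object of class `"sogl_cox"` with components including
#'   `lambda` (the path), `v` (latent coefficients, duplicated columns x
#'   lambda), `beta` (collapsed protein coefficients x lambda), `expansion`
#'   (the group bookkeeping), `cv` (fold assignment, per-fold losses, mean
#'   curve, selected lambda) and `selection` (proteins and pathways selected
#'   at the cross-validated lambda). Methods: [print.sogl_cox()],
#'   [summary.sogl_cox()], [coef.sogl_cox()], [predict.sogl_cox()],
#'   [plot.sogl_cox()].
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60 * 8), 60, 8,
#'             dimnames = list(NULL, paste0("P", 1:8)))
#' pw <- list(g1 = paste0("P", 1:4), g2 = paste0("P", 4:8))
#' tt <- rexp(60, exp(0.8 * x[, 1]))
#' fit <- sogl_cox(x, tt, rep(1, 60), pw, nfolds = 5, seed = 1)
#' fit
#' @export
sogl_cox <- function(x, time, event, pathways, alpha = 0.05, nlambda = 20,
                     lambda.min.ratio = 0.1,
                     group_weight = c("sqrt_size", "size"),
                     nfolds = 10, seed = NULL, tol = 1e-8, maxit = 10000L,
                     keep_design = TRUE) {
  cl <- match.call()
  x <- as.matrix(x)
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]")
  if (lambda.min.ratio <= 0 || lambda.min.ratio >= 1) {
    stop("`lambda.min.ratio` must lie in (0, 1)")
  }
  expansion <- expand_design(x, pathways, group_weight)
  prep <- .cox_prep(time, event)
  if (prep$n_events == 0L) stop("at least one event is required to fit the model")

  center <- colMeans(expansion$xtilde)
  scale_ <- apply(expansion$xtilde, 2, sd)
  if (any(scale_ == 0)) {
    bad <- unique(expansion$map$protein_id[scale_ == 0])
    stop("constant protein columns cannot be standardized: ",
         paste(head(bad, 5L), collapse = ", "))
  }
  xs <- sweep(sweep(expansion$xtilde, 2, center), 2, scale_, "/")

  lmax <- lambda_max(xs, time, event, alpha, expansion$groups, expansion$d_g)
  lambdas <- exp(seq(log(lmax), log(lmax * lambda.min.ratio),
                     length.out = nlambda))
  lambdas[1] <- lmax  # exp(log(.)) rounding must not undercut the entry point
  path <- .sogl_fit_path(xs, prep, expansion$groups, expansion$d_g, alpha,
                         lambdas, tol = tol, maxit = maxit)

  beta <- rowsum(path$v, group = expansion$map$protein_id, reorder = FALSE)
  rownames(beta) <- unique(expansion$map$protein_id)

  # per-protein standardization constants (identical across latent copies)
  fi <- !duplicated(expansion$map$protein_id)
  p_center <- setNames(center[fi], expansion$map$protein_id[fi])
  p_scale <- setNames(scale_[fi], expansion$map$protein_id[fi])

  cv <- NULL
  if (nfolds >= 2) {
    cv <- .sogl_cv(xs, time, event, expansion$groups, expansion$d_g, alpha,
                   lambdas, nfolds = nfolds, seed = seed,
                   tol = tol, maxit = maxit)
  }

  fit <- structure(list(
    call = cl, alpha = alpha, lambda = lambdas, v = path$v, beta = beta,
    objective = path$objective, expansion = expansion,
    center = p_center, scale = p_scale,
    nobs = prep$n, n_events = prep$n_events,
    time = time, event = as.integer(event != 0),
    xs = if (keep_design) xs else NULL,
    cv = cv
  ), class = "sogl_cox")
  fit$selection <- if (!is.null(cv)) selected_features(fit) else NULL
  fit
}

#' Selected proteins and pathways at a penalty level
#'
#' Collapses the latent coefficients of a fitted [sogl_cox()] model at a
#' penalty level (by default the cross-validated one) and reports the
#' "crucial" proteins (non-zero collapsed coefficient) and "dysregulated"
#' pathways (non-zero latent group norm). Because collapsing sums latent
#' copies, a protein whose copies cancel exactly has a zero collapsed
#' coefficient and is not selected even though its groups are.
#'
#' @param fit A fitted `"sogl_cox"` object.
#' @param lambda Penalty level; must be one of `fit$lambda`. Defaults to the
#'   cross-validated `lambda_min`.
#' @return A list with `proteins` (character), `pathways` (character),
#'   `beta` (named non-zero collapsed coefficients), `sign_label` (direction
#'   read-out per selected protein: coefficients below zero mean higher
#'   expression goes with longer survival), `lambda` and `index`.
#' @export
selected_features <- function(fit, lambda = NULL) {
  stopifnot(inherits(fit, "sogl_cox"))
  if (is.null(lambda)) {
    if (is.null(fit$cv)) stop("no cross-validation record: supply `lambda`")
    idx <- fit$cv$index
  } else {
    idx <- which(abs(fit$lambda - lambda) <= 1e-12 * max(fit$lambda))
    if (length(idx) != 1L) stop("`lambda` must be one value of fit$lambda")
  }
  beta <- fit$beta[, idx]
  v <- fit$v[, idx]
  norms <- vapply(fit$expansion$groups,
                  function(g) sqrt(sum(v[g]^2)), numeric(1))
  proteins <- rownames(fit$beta)[beta != 0]
  bsel <- beta[beta != 0]
  list(
    proteins = proteins,
    pathways = fit$expansion$pathway_ids[norms > 0],
    beta = bsel,
    sign_label = ifelse(bsel < 0,
                        "higher expression, longer survival",
                        "higher expression, shorter survival"),
    lambda = fit$lambda[idx],
    index = idx
  )
}
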