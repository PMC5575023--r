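# S3 methods for fitted sogl_cox objects.

#' @export
print.sogl_cox <- function(x, ...) {
  cat("Sparse overlapping group lasso Cox model\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("  %d samples (%d events), %d proteins in %d pathways (%d latent columns)\n",
              x$nobs, x$n_events, length(x$expansion$protein_ids),
              length(x$expansion$groups), ncol(x$xs %||% x$v)))
  cat(sprintf("  alpha = %g, path of %d lambdas in [%.4g, %.4g]\n",
              x$alpha, length(x$lambda), min(x$lambda), max(x$lambda)))
  if (!is.null(x$cv)) {
    cat(sprintf("  CV-selected lambda = %.4g (index %d of %d)\n",
                x$cv$lambda_min, x$cv$index, length(x$lambda)))
    sel <- x$selection
    cat(sprintf("  selected: %d proteins, %d pathways\n",
                length(sel$proteins), length(sel$pathways)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summary of a fitted SOGL Cox model
#'
#' @param object A fitted `"sogl_cox"` object.
#' @param lambda Penalty level, defaulting to the cross-validated one.
#' @param ... Unused.
#' @return An object of class `"summary.sogl_cox"` containing the selection
#'   and a per-protein coefficient table (protein, collapsed coefficient,
#'   direction label, pathways carrying a non-zero latent copy).
#' @export
summary.sogl_cox <- function(object, lambda = NULL, ...) {
  sel <- selected_features(object, lambda = lambda)
  v <- object$v[, sel$index]
  map <- object$expansion$map
  tab <- NULL
  if (length(sel$proteins)) {
    pw <- vapply(sel$proteins, function(p) {
      rows <- map$protein_id == p & v[map$column] != 0
      paste(unique(map$pathway_id[rows]), collapse = ";")
    }, character(1))
    tab <- data.frame(
      protein_id = sel$proteins,
      beta = unname(sel$beta),
      direction = unname(sel$sign_label),
      pathways = unname(pw),
      stringsAsFactors = FALSE
    )
    tab <- tab[order(abs(tab$beta), decreasing = TRUE), ]
    rownames(tab) <- NULL
  }
  structure(list(selection = sel, coefficients = tab,
                 lambda = sel$lambda, alpha = object$alpha),
            class = "summary.sogl_cox")
}

#' @export
print.summary.sogl_cox <- function(x, ...) {
  cat(sprintf("SOGL Cox selection at lambda = %.4g (alpha = %g)\n",
              x$lambda, x$alpha))
  cat(sprintf("Dysregulated pathways (%d): %s\n",
              length(x$selection$pathways),
              paste(x$selection$pathways, collapse = ", ")))
  if (is.null(x$coefficients)) {
    cat("No proteins selected.\n")
  } else {
    cat(sprintf("Crucial proteins (%d):\n", nrow(x$coefficients)))
    print(x$coefficients, digits = 4)
  }
  invisible(x)
}

#' Coefficients of a fitted SOGL Cox model
#'
#' @param object A fitted `"sogl_cox"` object.
#' @param lambda Penalty level (one of `object$lambda`); default the
#'   cross-validated one, or the full path when `lambda = "all"`.
#' @param type `"collapsed"` (per-protein sums of latent copies, default) or
#'   `"latent"` (per (protein, pathway) copy).
#' @param ... Unused.
#' @return A named numeric vector, or a matrix when `lambda = "all"`.
#'   Coefficients are on the standardized expression scale.
#' @export
coef.sogl_cox <- function(object, lambda = NULL, type = c("collapsed", "latent"),
                          ...) {
  type <- match.arg(type)
  m <- if (type == "collapsed") object$beta else object$v
  if (type == "latent") {
    rownames(m) <- paste(object$expansion$map$protein_id,
                         object$expansion$map$pathway_id, sep = "@")
  }
  if (identical(lambda, "all")) {
    colnames(m) <- signif(object$lambda, 6)
    return(m)
  }
  sel <- selected_features(object, lambda = lambda)
  m[, sel$index]
}

#' Linear predictor of a fitted SOGL Cox model
#'
#' New expression values are standardized with the centres and scales stored
#' at fit time, then multiplied by the collapsed protein coefficients
#' (latent copies of a protein share the standardization, so the collapsed
#' coefficients evaluate the same linear predictor as the latent ones).
#'
#' @param object A fitted `"sogl_cox"` object.
#' @param newx Matrix of protein abundances, samples x proteins, with
#'   column names covering the proteins used in the fit.
#' @param lambda Penalty level; defaults to the cross-validated one.
#' @param type `"lp"` (linear predictor, default) or `"risk"` (its exp).
#' @param ... Unused.
#' @return Numeric vector, one value per row of `newx`.
#' @export
predict.sogl_cox <- function(object, newx, lambda = NULL,
                             type = c("lp", "risk"), ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  ids <- names(object$center)
  if (!all(ids %in% colnames(newx))) {
    stop("`newx` must contain all proteins used in the fit")
  }
  beta <- coef(object, lambda = lambda, type = "collapsed")
  xs <- sweep(sweep(newx[, ids, drop = FALSE], 2, object$center), 2,
              object$scale, "/")
  lp <- drop(xs %*% beta[ids])
  if (type == "risk") exp(lp) else lp
}

#' Plot a fitted SOGL Cox model
#'
#' `type = "cv"` draws the cross-validated partial-likelihood contrast
#' against log(lambda) with the selected level marked; `type = "path"` draws
#' the collapsed coefficient paths.
#'
#' @param x A fitted `"sogl_cox"` object.
#' @param type `"cv"` or `"path"`.
#' @param ... Passed on to the base plotting calls.
#' @return The object, invisibly.
#' @export
plot.sogl_cox <- function(x, type = c("cv", "path"), ...) {
  type <- match.arg(type)
  ll <- log(x$lambda)
  if (type == "cv") {
    if (is.null(x$cv)) stop("no cross-validation record to plot")
    plot(ll, x$cv$cvm, type = "b", pch = 19,
         xlab = expression(log(lambda)),
         ylab = "CV partial-likelihood contrast", ...)
    abline(v = log(x$cv$lambda_min), lty = 2)
  } else {
    matplot(ll, t(x$beta), type = "l", lty = 1,
            xlab = expression(log(lambda)),
            ylab = "collapsed coefficient", ...)
    abline(h = 0, col = "grey")
    if (!is.null(x$cv)) abline(v = log(x$cv$lambda_min), lty = 2)
  }
  invisible(x)
}
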