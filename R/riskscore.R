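# Pathway scores, predictive-protein selection and protein-driven risk
# scores built on top of a fitted SOGL Cox model.

#' Pathway score from SOGL latent coefficients
#'
#' The relative pathway score is the linear combination of the pathway's
#' (standardized) member expression weighted by the pathway's latent SOGL
#' coefficients at the chosen penalty level:
#' \eqn{\mathrm{score}_g(x) = \sum_{j \in g} \hat{\tilde v}^g_j \,
#' x^{scaled}_j}.
#'
#' @param fit A fitted [sogl_cox()] model (with `keep_design = TRUE` when
#'   `newx` is omitted).
#' @param pathway_id One pathway of the fit.
#' @param newx Optional samples x proteins matrix; defaults to the fit's own
#'   design.
#' @param lambda Penalty level; defaults to the cross-validated one.
#' @return Numeric score per sample.
#' @export
pathway_score <- function(fit, pathway_id, newx = NULL, lambda = NULL) {
  stopifnot(inherits(fit, "sogl_cox"))
  k <- match(pathway_id, fit$expansion$pathway_ids)
  if (is.na(k)) stop("unknown pathway: ", pathway_id)
  sel <- selected_features(fit, lambda = lambda)
  g <- fit$expansion$groups[[k]]
  v <- fit$v[g, sel$index]
  if (all(v == 0)) {
    stop("pathway '", pathway_id,
         "' has an all-zero latent block at this lambda; its score is undefined")
  }
  members <- fit$expansion$map$protein_id[g]
  if (is.null(newx)) {
    if (is.null(fit$xs)) stop("fit was built with keep_design = FALSE; supply `newx`")
    xs <- fit$xs[, g, drop = FALSE]
  } else {
    newx <- as.matrix(newx)
    if (!all(members %in% colnames(newx))) {
      stop("`newx` must contain all members of the pathway")
    }
    xs <- sweep(sweep(newx[, members, drop = FALSE], 2, fit$center[members]),
                2, fit$scale[members], "/")
  }
  drop(xs %*% v)
}

#' Per-pathway time-dependent AUC table
#'
#' Scores every pathway selected at the cross-validated penalty level with
#' [pathway_score()] and evaluates its apparent (in-sample) time-dependent
#' AUC at horizon `t` against the fit's own outcome.
#'
#' @param fit A fitted [sogl_cox()] model with a cross-validation record.
#' @param t Horizon time.
#' @return Data frame `pathway_id`, `n_nonzero` (latent non-zeros), `auc`,
#'   sorted by decreasing AUC.
#' @export
pathway_auc_table <- function(fit, t) {
  stopifnot(inherits(fit, "sogl_cox"))
  sel <- selected_features(fit)
  if (!length(sel$pathways)) stop("no pathway selected at the CV lambda")
  rows <- lapply(sel$pathways, function(pid) {
    sc <- pathway_score(fit, pid)
    a <- td_roc(sc, fit$time, fit$event, t)$auc
    k <- match(pid, fit$expansion$pathway_ids)
    nz <- sum(fit$v[fit$expansion$groups[[k]], sel$index] != 0)
    data.frame(pathway_id = pid, n_nonzero = nz, auc = max(a, 1 - a),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$auc, decreasing = TRUE), , drop = FALSE]
}

#' Select predictive proteins by univariate AUC and redundancy filtering
#'
#' Ranks candidate proteins by their univariate time-dependent AUC at
#' horizon `t` (orientation-free: a marker and its negation discriminate
#' equally, so `max(auc, 1 - auc)` is used), keeps those above `auc_min`,
#' and greedily filters in descending AUC order so that every retained pair
#' has absolute Spearman correlation below `cc_max`.
#'
#' @param candidates Character vector of candidate proteins (typically the
#'   crucial proteins of a SOGL fit).
#' @param x Samples x proteins matrix.
#' @param time,event Survival outcome.
#' @param t Horizon.
#' @param auc_min AUC threshold (default 0.90).
#' @param cc_max Absolute Spearman correlation ceiling (default 0.30).
#' @return Character vector of retained proteins (possibly empty), with the
#'   per-candidate AUC table as attribute `"auc"`.
#' @export
select_predictive_proteins <- function(candidates, x, time, event, t,
                                       auc_min = 0.90, cc_max = 0.30) {
  if (!length(candidates)) stop("empty candidate set")
  x <- as.matrix(x)
  if (!all(candidates %in% colnames(x))) {
    stop("candidates must be columns of `x`")
  }
  auc <- vapply(candidates, function(p) {
    a <- td_roc(x[, p], time, event, t)$auc
    max(a, 1 - a)
  }, numeric(1))
  ord <- order(auc, decreasing = TRUE)
  keep <- character(0)
  for (p in candidates[ord]) {
    if (auc[p] <= auc_min) next
    redundant <- any(vapply(keep, function(q) {
      abs(cor(x[, p], x[, q], method = "spearman")) >= cc_max
    }, logical(1)))
    if (!redundant) keep <- c(keep, p)
  }
  structure(keep, auc = auc)
}

#' Protein-panel risk score
#'
#' A risk score is a linear combination of scaled protein expression,
#' \eqn{\mathrm{score} = \sum_j w_j x^{scaled}_j}. `risk_score()` builds one
#' from known weights; [build_risk_score()] estimates the weights as the
#' multivariable Cox regression coefficients of the panel.
#'
#' @param weights Named numeric vector of per-protein weights.
#' @param center,scale Per-protein standardization constants applied to new
#'   expression before weighting; the defaults (0 and 1) assume expression
#'   is already scaled.
#' @param endpoint Label, e.g. `"os"` or `"pfs"`.
#' @return An object of class `"risk_score"`.
#' @export
risk_score <- function(weights, center = 0, scale = 1, endpoint = "os") {
  if (!length(weights) || is.null(names(weights))) {
    stop("`weights` must be a named, non-empty vector")
  }
  panel <- names(weights)
  center <- rep_len(center, length(panel))
  scale <- rep_len(scale, length(panel))
  structure(list(panel = panel, weights = unname(weights),
                 center = setNames(center, panel),
                 scale = setNames(scale, panel), endpoint = endpoint),
            class = "risk_score")
}

#' @export
print.risk_score <- function(x, ...) {
  cat(sprintf("risk score (%s): %s\n", x$endpoint,
              paste(sprintf("(%.3f x %s)", x$weights, x$panel),
                    collapse = " + ")))
  invisible(x)
}

#' Evaluate a risk score on expression data
#'
#' @param object A [risk_score()].
#' @param newx Samples x proteins matrix containing the panel columns.
#' @param ... Unused.
#' @return Numeric score per sample.
#' @export
predict.risk_score <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  if (!all(object$panel %in% colnames(newx))) {
    stop("`newx` must contain the panel proteins")
  }
  xs <- sweep(sweep(newx[, object$panel, drop = FALSE], 2, object$center),
              2, object$scale, "/")
  drop(xs %*% object$weights)
}

#' Estimate a protein-driven risk score by Cox regression
#'
#' Scales the panel expression to zero mean / unit variance, fits a
#' multivariable Cox proportional hazards model (Breslow ties) of the
#' endpoint on the scaled panel, and uses the fitted coefficients as the
#' score weights.
#'
#' @param panel Character vector of protein identifiers (non-empty).
#' @param x Samples x proteins matrix.
#' @param time,event Endpoint outcome.
#' @param endpoint Label stored on the score.
#' @return A [risk_score()] whose `score` attribute holds the in-sample
#'   scores for the rows of `x`.
#' @export
build_risk_score <- function(panel, x, time, event, endpoint = "os") {
  if (!length(panel)) stop("empty panel")
  x <- as.matrix(x)
  if (!all(panel %in% colnames(x))) stop("panel proteins missing from `x`")
  xp <- x[, panel, drop = FALSE]
  ctr <- colMeans(xp)
  scl <- apply(xp, 2, sd)
  if (any(scl == 0)) stop("constant panel protein cannot be scaled")
  xs <- sweep(sweep(xp, 2, ctr), 2, scl, "/")
  df <- as.data.frame(xs)
  names(df) <- make.names(panel)
  fit <- tryCatch(
    coxph(Surv(time, event) ~ ., data = df, ties = "breslow",
          control = coxph.control(iter.max = 50)),
    warning = function(w) stop("Cox regression did not converge: ",
                               conditionMessage(w)),
    error = function(e) stop("Cox regression failed: ", conditionMessage(e))
  )
  w <- setNames(coef(fit), panel)
  rs <- risk_score(w, center = ctr, scale = scl, endpoint = endpoint)
  attr(rs, "score") <- drop(xs %*% rs$weights)
  attr(rs, "cox_fit") <- fit
  rs
}
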