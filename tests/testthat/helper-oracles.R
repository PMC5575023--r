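# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (loops, enumeration, generic optimizers)
# and never call the package's own code paths.

# Negative log Cox partial likelihood, term by term (Breslow ties).
oracle_cox_nll <- function(v, x, time, event) {
  eta <- drop(as.matrix(x) %*% v)
  n <- length(time)
  total <- 0
  for (i in seq_len(n)) {
    if (event[i] == 1) {
      risk <- which(time >= time[i])
      total <- total + log(sum(exp(eta[risk]))) - eta[i]
    }
  }
  total / n
}

# Prox objective minimized with BFGS on a smoothed surrogate (|v| and
# ||v_g|| replaced by sqrt(. + eps)), with analytic gradients and a
# continuation schedule eps -> 0 so the kinks do not stall the optimizer.
# Strong convexity (modulus 1) turns an objective gap into a bound on the
# distance to the true prox point.
oracle_prox <- function(z, groups, step, lambda, alpha, d_g) {
  sl <- step * lambda
  obj <- function(v, eps) {
    pen <- alpha * sum(sqrt(v^2 + eps))
    for (k in seq_along(groups)) {
      pen <- pen + (1 - alpha) * d_g[k] * sqrt(sum(v[groups[[k]]]^2) + eps)
    }
    0.5 * sum((v - z)^2) + sl * pen
  }
  grad <- function(v, eps) {
    g <- (v - z) + sl * alpha * v / sqrt(v^2 + eps)
    for (k in seq_along(groups)) {
      gk <- groups[[k]]
      g[gk] <- g[gk] +
        sl * (1 - alpha) * d_g[k] * v[gk] / sqrt(sum(v[gk]^2) + eps)
    }
    g
  }
  run <- function(start) {
    v <- start
    for (eps in c(1e-4, 1e-8, 1e-12, 1e-16, 1e-20)) {
      v <- optim(v, obj, grad, eps = eps, method = "BFGS",
                 control = list(reltol = 1e-16, maxit = 10000))$par
    }
    v
  }
  cands <- list(run(z), run(numeric(length(z))))
  vals <- vapply(cands, obj, numeric(1), eps = 0)
  cands[[which.min(vals)]]
}

# Upper-tail hypergeometric probability by exact enumeration of the tail.
oracle_hyper_tail <- function(k_obs, m, n_univ, k_draw) {
  kk <- k_obs:min(m, k_draw)
  sum(choose(m, kk) * choose(n_univ - m, k_draw - kk)) / choose(n_univ, k_draw)
}

# Mann-Whitney AUC of a marker against a binary status, ties counted half.
oracle_mw_auc <- function(marker, status) {
  x1 <- marker[status == 1]
  x0 <- marker[status == 0]
  s <- 0
  for (a in x1) s <- s + sum(a > x0) + 0.5 * sum(a == x0)
  s / (length(x1) * length(x0))
}

# From-the-definition cumulative/dynamic ROC(t): KM via survival::survfit
# (a different code path from the package's internal product-limit helper),
# plug-in sensitivity/specificity, cumulative-max repair, trapezoid.
oracle_td_auc <- function(marker, time, event, t) {
  km_surv <- function(tt, ee, at) {
    if (!length(tt)) return(1)
    f <- survival::survfit(survival::Surv(tt, ee) ~ 1)
    s <- summary(f, times = at, extend = TRUE)$surv
    if (!length(s)) 1 else s
  }
  st <- km_surv(time, event, t)
  cs <- sort(unique(marker))
  sens <- spec <- numeric(length(cs))
  for (i in seq_along(cs)) {
    hi <- marker > cs[i]
    p1 <- mean(hi)
    sens[i] <- if (p1 > 0) (1 - km_surv(time[hi], event[hi], t)) * p1 / (1 - st) else 0
    spec[i] <- if (p1 < 1) km_surv(time[!hi], event[!hi], t) * (1 - p1) / st else 0
  }
  sens <- pmin(pmax(sens, 0), 1)
  spec <- pmin(pmax(spec, 0), 1)
  fpr <- cummax(c(0, rev(1 - spec), 1))
  tpr <- cummax(c(0, rev(sens), 1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Small standardized design + grouped pathways for solver tests.
make_fixture <- function(n = 50, p = 10, seed = 1, n_events = NULL) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("P%02d", 1:p)))
  beta <- c(1, -0.8, 0.5, rep(0, p - 3))
  tt <- rexp(n, exp(drop(x %*% beta)))
  ev <- rbinom(n, 1, 0.8)
  if (sum(ev) == 0) ev[1] <- 1
  list(x = x, time = tt, event = ev, beta = beta)
}

singleton_pathways <- function(x) {
  setNames(lapply(colnames(x), identity), paste0("g_", colnames(x)))
}
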