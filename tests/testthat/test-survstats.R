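# Kaplan-Meier, log-rank, Cox wrappers and risk grouping.

test_that("KM hand fixtures: all events, censoring, and the no-event curve", {
  km1 <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km1$survival, c(2 / 3, 1 / 3, 0))
  # times (1, 2+, 3): S(1) = 2/3, S(3) = 2/3 * (1 - 1/1) = 0
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$event_times, c(1, 3))
  expect_equal(km2$survival, c(2 / 3, 0))
  expect_equal(km_survival(km2, c(0.5, 1, 2.5, 3)), c(1, 2 / 3, 2 / 3, 0))
  km0 <- km_estimate(c(1, 2), c(0, 0))
  expect_length(km0$event_times, 0)
  expect_equal(km_survival(km0, c(1, 5)), c(1, 1))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("KM without censoring equals one minus the empirical CDF", {
  set.seed(31)
  tt <- round(rexp(40), 2)
  km <- km_estimate(tt, rep(1, 40))
  for (t0 in unique(tt)) {
    expect_equal(km_survival(km, t0), mean(tt > t0), tolerance = 1e-12)
  }
})

test_that("log-rank statistic equals the tabulated O-E computation", {
  # two-group fixture, hand-enumerable
  tt <- c(3, 5, 7, 9, 11, 2, 4, 6, 8, 10)
  ev <- c(1, 1, 0, 1, 1, 1, 1, 1, 0, 1)
  gr <- rep(c("a", "b"), each = 5)
  lr <- logrank_test(tt, ev, gr)
  # independent O-E / V tabulation over event times
  o_minus_e <- 0; v <- 0
  for (t0 in sort(unique(tt[ev == 1]))) {
    at <- tt >= t0
    d <- sum(tt == t0 & ev == 1)
    n_at <- sum(at)
    n1 <- sum(at & gr == "a")
    d1 <- sum(tt == t0 & ev == 1 & gr == "a")
    o_minus_e <- o_minus_e + d1 - d * n1 / n_at
    if (n_at > 1) {
      v <- v + d * (n1 / n_at) * (1 - n1 / n_at) * (n_at - d) / (n_at - 1)
    }
  }
  expect_equal(lr$chi_square, o_minus_e^2 / v, tolerance = 1e-10)
  expect_equal(lr$df, 1L)
  expect_equal(lr$p_value, pchisq(o_minus_e^2 / v, 1, lower.tail = FALSE))
  # identical groups -> statistic 0, p 1
  same <- logrank_test(c(tt, tt), c(ev, ev), rep(c("x", "y"), each = 10))
  expect_lt(same$chi_square, 1e-10)
  expect_equal(same$p_value, 1, tolerance = 1e-6)
  # three groups -> 2 degrees of freedom; single group errors
  expect_equal(logrank_test(tt, ev, rep(c("a", "b", "c"), c(3, 3, 4)))$df, 2L)
  expect_error(logrank_test(tt, ev, rep("a", 10)), "two groups")
})

test_that("two-group log-rank equals the Cox score test at beta = 0", {
  set.seed(32)
  tt <- rexp(60)
  ev <- rbinom(60, 1, 0.7)
  g <- rbinom(60, 1, 0.5)
  lr <- logrank_test(tt, ev, g)
  sc <- summary(survival::coxph(survival::Surv(tt, ev) ~ g,
                                ties = "breslow"))$sctest[["test"]]
  expect_equal(lr$chi_square, sc, tolerance = 1e-8)
})

test_that("Cox coefficient matches direct maximization of the partial likelihood", {
  set.seed(33)
  n <- 40
  z <- rbinom(n, 1, 0.5)
  tt <- rexp(n, exp(0.8 * z))
  ev <- rbinom(n, 1, 0.85)
  fit <- cox_fit(tt, ev, data.frame(z = z))
  direct <- optimize(function(b) oracle_cox_nll(b, matrix(z), tt, ev),
                     c(-5, 5), tol = 1e-10)$minimum
  expect_equal(fit$table$coef, direct, tolerance = 1e-6)
  expect_equal(fit$table$hr, exp(fit$table$coef), tolerance = 1e-12)
  expect_true(fit$table$ci_low < fit$table$hr & fit$table$hr < fit$table$ci_high)
})

test_that("Cox estimates are invariant to duplicating the dataset", {
  set.seed(34)
  n <- 50
  z <- rnorm(n)
  tt <- rexp(n, exp(0.5 * z))
  ev <- rbinom(n, 1, 0.8)
  f1 <- cox_fit(tt, ev, data.frame(z = z))
  f2 <- cox_fit(rep(tt, 2), rep(ev, 2), data.frame(z = rep(z, 2)))
  expect_equal(f1$table$coef, f2$table$coef, tolerance = 1e-6)
  expect_error(cox_fit(tt, ev, data.frame(k = rep(1, n))), "constant")
})

test_that("null Cox p-values are uniform (calibration)", {
  set.seed(35)
  pv <- vapply(1:200, function(r) {
    n <- 120
    z <- rnorm(n)
    tt <- rexp(n)
    ev <- rbinom(n, 1, 0.8)
    cox_fit(tt, ev, data.frame(z = z))$table$p_value
  }, numeric(1))
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("univariate screen keeps strong factors and passes nulls at ~5%", {
  set.seed(36)
  n <- 200
  strong <- rnorm(n)
  nulls <- matrix(rnorm(n * 8), n, dimnames = list(NULL, paste0("n", 1:8)))
  tt <- rexp(n, exp(2 * strong))
  ev <- rbinom(n, 1, 0.85)
  scr <- univariate_screen(tt, ev, data.frame(strong = strong, nulls))
  expect_true("strong" %in% scr$selected)
  none <- univariate_screen(tt, ev, as.data.frame(nulls), threshold = 1e-12)
  expect_length(none$selected, 0)
})

test_that("risk groups follow the type-7 quartile rule", {
  g <- risk_groups(1:100)
  expect_equal(as.vector(table(g)), c(25, 50, 25))
  g4 <- risk_groups(c(10, 20, 30, 40))
  expect_equal(as.vector(table(g4)), c(1, 2, 1))
  expect_error(risk_groups(rep(2, 10)), "equal")
  expect_error(risk_groups(c(1, 2, 3)), "at least 4")
})
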