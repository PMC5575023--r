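# Design expansion, path entry point, solver cross-checks and the collapse
# identity of the latent-duplication formulation.

test_that("expansion width counts (protein, pathway) memberships", {
  x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  disjoint <- expand_design(x, list(g1 = c("a", "b"), g2 = c("c", "d")))
  expect_equal(ncol(disjoint$xtilde), 4)

  x3 <- x[, 1:3]
  shared <- expand_design(x3, list(g1 = c("a", "b"), g2 = c("b", "c")))
  expect_equal(ncol(shared$xtilde), 4)  # 3 proteins + 1 duplicate
  expect_equal(nrow(shared$map), 4)
  expect_true(!anyDuplicated(shared$map[c("protein_id", "pathway_id")]))
  # duplicated columns carry the protein's values
  expect_equal(unname(shared$xtilde[, 2]), unname(shared$xtilde[, 3]))
  expect_error(expand_design(x3, list(g = c("a", "zzz"))), "absent")
})

test_that("collapse map on overlapping groups is verified by enumeration", {
  set.seed(3)
  x <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, sprintf("P%02d", 1:10)))
  pw <- list(g1 = sprintf("P%02d", 1:4), g2 = sprintf("P%02d", 3:6),
             g3 = sprintf("P%02d", c(1, 6:9)))
  ex <- expand_design(x, pw)
  expect_equal(ncol(ex$xtilde), 4 + 4 + 5)
  v <- rnorm(13)
  collapsed <- rowsum(v, ex$map$protein_id, reorder = FALSE)
  manual <- sapply(unique(ex$map$protein_id), function(p) {
    sum(v[ex$map$protein_id == p])
  })
  expect_equal(drop(collapsed), manual, ignore_attr = TRUE)
})

test_that("path starts at zero; fits appear at half lambda_max; homogeneity", {
  fx <- make_fixture(n = 60, p = 8, seed = 7)
  pw <- list(g1 = colnames(fx$x)[1:4], g2 = colnames(fx$x)[4:8])
  fit <- sogl_cox(fx$x, fx$time, fx$event, pw, nfolds = 0)
  expect_true(all(fit$v[, 1] == 0))
  expect_true(all(fit$beta[, 1] == 0))

  ex <- expand_design(fx$x, pw)
  xs <- scale(ex$xtilde)
  lm1 <- lambda_max(xs, fx$time, fx$event, 0.05, ex$groups, ex$d_g)
  sol <- soglcox:::.sogl_solve(xs, soglcox:::.cox_prep(fx$time, fx$event),
                               ex$groups, ex$d_g, 0.5 * lm1, 0.05,
                               numeric(ncol(xs)))
  expect_gt(sum(sol$v != 0), 0)
  # doubling the design doubles the entry point
  lm2 <- lambda_max(2 * xs, fx$time, fx$event, 0.05, ex$groups, ex$d_g)
  expect_equal(lm2, 2 * lm1, tolerance = 1e-6)
  expect_error(lambda_max(cbind(xs, 1), fx$time, fx$event, 0.05,
                          c(ex$groups, list(ncol(xs) + 1L)), c(ex$d_g, 1)),
               "constant")
})

test_that("alpha = 1 with singleton groups matches an independent lasso-Cox solver", {
  skip_if_not_installed("glmnet")
  fx <- make_fixture(n = 50, p = 10, seed = 42)
  fit <- sogl_cox(fx$x, fx$time, fx$event, singleton_pathways(fx$x),
                  alpha = 1, nfolds = 0, tol = 1e-12)
  xstd <- scale(fx$x)
  g <- glmnet::glmnet(xstd, survival::Surv(fx$time, fx$event),
                      family = "cox", alpha = 1, lambda = fit$lambda,
                      standardize = FALSE, thresh = 1e-14, maxit = 1e6)
  expect_lt(max(abs(fit$beta[colnames(fx$x), ] - as.matrix(coef(g)))), 1e-4)
})

test_that("alpha = 0 with singleton groups is the lasso up to the group weight", {
  fx <- make_fixture(n = 50, p = 6, seed = 9)
  pw <- singleton_pathways(fx$x)
  f0 <- sogl_cox(fx$x, fx$time, fx$event, pw, alpha = 0, nfolds = 0,
                 tol = 1e-12)
  f1 <- sogl_cox(fx$x, fx$time, fx$event, pw, alpha = 1, nfolds = 0,
                 tol = 1e-12)
  # singleton groups with d_g = 1: the two penalties coincide
  expect_equal(max(f0$lambda), max(f1$lambda), tolerance = 1e-8)
  expect_equal(f0$beta, f1$beta, tolerance = 1e-6)
})

test_that("solutions are local optima and improve on the null fit", {
  fx <- make_fixture(n = 15, p = 4, seed = 13)
  pw <- list(g1 = colnames(fx$x)[1:2], g2 = colnames(fx$x)[2:4])
  fit <- sogl_cox(fx$x, fx$time, fx$event, pw, nfolds = 0, tol = 1e-10)
  ex <- fit$expansion
  xs <- fit$xs
  prep <- soglcox:::.cox_prep(fx$time, fx$event)
  objective <- function(v, lam) {
    soglcox:::.cox_nll_eta(drop(xs %*% v), prep) +
      soglcox:::.sogl_penalty(v, ex$groups, ex$d_g, fit$alpha, lam)
  }
  set.seed(99)
  for (i in c(5L, 20L)) {
    v <- fit$v[, i]
    lam <- fit$lambda[i]
    f0 <- objective(v, lam)
    expect_lte(f0, objective(numeric(length(v)), lam) + 1e-10)
    pert <- replicate(300, objective(v + rnorm(length(v), sd = 1e-2), lam))
    expect_true(all(pert >= f0 - 1e-9))
  }
})

test_that("collapse identity beta = sum of latent copies holds on every lambda", {
  fx <- make_fixture(n = 60, p = 8, seed = 17)
  pw <- list(g1 = colnames(fx$x)[1:5], g2 = colnames(fx$x)[4:8],
             g3 = colnames(fx$x)[c(1, 8)])
  fit <- sogl_cox(fx$x, fx$time, fx$event, pw, nfolds = 0)
  for (i in seq_along(fit$lambda)) {
    manual <- rowsum(fit$v[, i], fit$expansion$map$protein_id, reorder = FALSE)
    expect_equal(fit$beta[, i], drop(manual), ignore_attr = TRUE)
  }
})

test_that("objective is non-increasing along solver iterations (monotone descent)", {
  # indirectly: solution objective never exceeds the warm-start objective
  fx <- make_fixture(n = 40, p = 6, seed = 23)
  fit <- sogl_cox(fx$x, fx$time, fx$event,
                  list(g1 = colnames(fx$x)[1:3], g2 = colnames(fx$x)[3:6]),
                  nfolds = 0)
  expect_true(all(diff(fit$objective) <= 1e-10))
})
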