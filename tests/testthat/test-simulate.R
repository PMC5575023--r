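# Synthetic cohort generator: determinism, overlap structure, bridge
# mechanics and the survival data-generating process.

test_that("identical configurations reproduce identical cohorts", {
  cfg <- sim_config(n_proteins = 40, n_pathways = 4, seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$pathways$sets, b$pathways$sets)
  expect_identical(a$truth$true_beta, b$truth$true_beta)
})

test_that("pathway generation honours overlap and size constraints", {
  # no overlap: every protein in at most one pathway
  cfg0 <- sim_config(n_proteins = 80, n_pathways = 5,
                     pathway_size_range = c(8, 12), overlap_fraction = 0,
                     seed = 2)
  pw0 <- generate_pathways(cfg0)
  memb <- table(unlist(pw0$sets))
  expect_true(all(memb <= 1))
  # degenerate single pathway covering the universe
  cfg1 <- sim_config(n_proteins = 10, n_pathways = 1,
                     pathway_size_range = c(10, 10), overlap_fraction = 0,
                     n_active_pathways = 1, seed = 3)
  pw1 <- generate_pathways(cfg1)
  expect_setequal(pw1$sets[[1]], pw1$universe)
  # measured overlap within +/- 0.1 of the target
  cfg2 <- sim_config(n_proteins = 200, n_pathways = 12,
                     pathway_size_range = c(10, 20), overlap_fraction = 0.4,
                     seed = 4)
  pw2 <- generate_pathways(cfg2)
  memb2 <- table(unlist(pw2$sets))
  expect_lt(abs(mean(memb2 >= 2) - 0.4), 0.1)
  sz <- lengths(pw2$sets)
  expect_true(all(sz >= 10 & sz <= 20))
  # infeasible tiling is rejected
  cfg_bad <- sim_config(n_proteins = 10, n_pathways = 5,
                        pathway_size_range = c(8, 8), overlap_fraction = 0,
                        seed = 1)
  expect_error(generate_pathways(cfg_bad), "infeasible")
})

test_that("bridge records differ only by shift and noise; zero-noise twins match", {
  cfg <- sim_config(n_site_a = 20, n_site_b = 15, n_bridge = 6,
                    n_proteins = 30, n_pathways = 3,
                    pathway_size_range = c(5, 8), n_active_per_pathway = 3, batch_shift_sd = 0,
                    noise_sd = 0, seed = 6)
  pw <- generate_pathways(cfg)
  truth <- generate_truth(cfg, pw)
  pm <- generate_expression(cfg, truth)
  for (s in pm$bridge_ids) {
    cols <- which(pm$sample_ids == s)
    expect_length(cols, 2)
    expect_equal(pm$values[, cols[1]], pm$values[, cols[2]])
  }
  # no bridges -> no duplicate records
  cfg0 <- sim_config(n_site_a = 10, n_site_b = 8, n_bridge = 0,
                     n_proteins = 30, n_pathways = 3,
                     pathway_size_range = c(5, 8), n_active_per_pathway = 3, seed = 6)
  pm0 <- generate_expression(cfg0, generate_truth(cfg0, generate_pathways(cfg0)))
  expect_false(anyDuplicated(pm0$sample_ids) > 0)
})

test_that("a constant planted site shift is recovered from bridge medians", {
  cfg <- sim_config(n_site_a = 40, n_site_b = 35, n_bridge = 20,
                    n_proteins = 25, n_pathways = 3,
                    pathway_size_range = c(5, 8), n_active_per_pathway = 3, batch_shift_sd = 0,
                    noise_sd = 0.1, seed = 7)
  pw <- generate_pathways(cfg)
  truth <- generate_truth(cfg, pw)
  truth$site_shift[] <- 1.7
  pm <- generate_expression(cfg, truth)
  ba <- pm$sample_ids %in% pm$bridge_ids & pm$site == "A"
  bb <- pm$sample_ids %in% pm$bridge_ids & pm$site == "B"
  dmed <- apply(pm$values[, bb], 1, median) - apply(pm$values[, ba], 1, median)
  expect_equal(median(dmed), 1.7, tolerance = 0.1)
})

test_that("with no site shift, per-protein distributions do not differ by site", {
  cfg <- sim_config(n_site_a = 60, n_site_b = 60, n_bridge = 0,
                    n_proteins = 50, n_pathways = 5,
                    pathway_size_range = c(8, 12), batch_shift_sd = 0,
                    noise_sd = 0.3, seed = 8)
  pm <- generate_expression(cfg, generate_truth(cfg, generate_pathways(cfg)))
  a <- pm$site == "A"
  p_ks <- vapply(seq_len(nrow(pm$values)), function(i) {
    suppressWarnings(ks.test(pm$values[i, a], pm$values[i, !a])$p.value)
  }, numeric(1))
  expect_gte(mean(p_ks > 0.01 / length(p_ks)), 0.95)
})

test_that("censoring calibration hits the target and censor_rate 0 keeps all events", {
  cfg <- sim_config(seed = 9, censor_rate = 0.3)
  co <- simulate_cohort(cfg)
  expect_lt(abs(mean(co$clinical$os_event == 0) - 0.3), 0.05 + 1e-9)
  cfg0 <- sim_config(seed = 9, censor_rate = 0)
  co0 <- simulate_cohort(cfg0)
  expect_true(all(co0$clinical$os_event == 1))
})

test_that("survival under the null is exchangeable with expression (log-rank calibration)", {
  pvals <- vapply(1:150, function(r) {
    cfg <- sim_config(n_site_a = 40, n_site_b = 0, n_bridge = 0,
                      n_proteins = 5, n_pathways = 1,
                      pathway_size_range = c(5, 5), overlap_fraction = 0,
                      n_active_pathways = 1, n_active_per_pathway = 1,
                      effect_size = 0, censor_rate = 0.2,
                      batch_shift_sd = 0, noise_sd = 0, seed = 1000 + r)
    co <- simulate_cohort(cfg)
    g <- design_matrix(co$latent)[, 1] > 0
    logrank_test(co$clinical$os_time, co$clinical$os_event, g)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("a single strong protein yields high concordance with survival", {
  cfg <- sim_config(n_site_a = 200, n_site_b = 0, n_bridge = 0,
                    n_proteins = 5, n_pathways = 1,
                    pathway_size_range = c(5, 5), overlap_fraction = 0,
                    n_active_pathways = 1, n_active_per_pathway = 1,
                    effect_size = 2, censor_rate = 0.2,
                    batch_shift_sd = 0, noise_sd = 0, seed = 10)
  co <- simulate_cohort(cfg)
  p_active <- co$truth$active_proteins
  x <- design_matrix(co$latent)[, p_active] * sign(co$truth$true_beta[p_active])
  cc <- survival::concordance(
    survival::coxph(survival::Surv(co$clinical$os_time, co$clinical$os_event) ~ x)
  )$concordance
  expect_gte(cc, 0.8)
})

test_that("cohort round-trips through the TSV/GMT/JSON writers", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(sim_config(n_proteins = 30, n_pathways = 3,
                                   pathway_size_range = c(5, 8), n_active_per_pathway = 3, seed = 11))
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  pm <- read_protein_matrix(paths["expression"], paths["samples"])
  expect_equal(unname(pm$values), unname(co$expression$values),
               tolerance = 1e-12)
  expect_identical(pm$sample_ids, co$expression$sample_ids)
  expect_setequal(pm$bridge_ids, co$expression$bridge_ids)
  pw <- read_gmt(paths["gmt"])
  expect_identical(pw$sets, co$pathways$sets)
})
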