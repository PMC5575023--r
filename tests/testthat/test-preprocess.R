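# Median re-centering, bridge batch correction, missing-data exclusion and
# gene-level deduplication.

toy_pm <- function(values, site = NULL, bridge = character()) {
  protein_matrix(values,
                 protein_ids = sprintf("NP_%03d", seq_len(nrow(values))),
                 sample_ids = colnames(values), site = site,
                 bridge_ids = bridge)
}

test_that("median re-centering zeroes every sample median and is idempotent", {
  m <- matrix(c(1, 2, 3, 10, 20, 30), 3, 2,
              dimnames = list(NULL, c("s1", "s2")))
  pm <- median_recenter(toy_pm(m))
  expect_equal(unname(pm$values[, "s1"]), c(-1, 0, 1))
  expect_identical(median_recenter(pm)$values, pm$values)

  set.seed(1)
  r <- matrix(rnorm(35), 5, 7, dimnames = list(NULL, paste0("s", 1:7)))
  r[2, 3] <- NA
  pr <- median_recenter(toy_pm(r))
  expect_true(all(abs(apply(pr$values, 2, median, na.rm = TRUE)) < 1e-12))
})

test_that("bridge correction shifts site B by the bridge-median difference", {
  # protein p: bridge medians A = 5, B = 2 -> every site-B value shifted +3
  vals <- rbind(c(5, 6, 4, 2, 3, 1, 7, 0),
                c(0, 1, -1, 0, 1, -1, 2, 2))
  colnames(vals) <- c("b1", "b2", "b3", "b1", "b2", "b3", "a1", "c1")
  site <- c("A", "A", "A", "B", "B", "B", "A", "B")
  pm <- toy_pm(vals, site = site, bridge = c("b1", "b2", "b3"))
  out <- batch_correct_bridge(pm)
  # site-A values untouched
  expect_equal(unname(out$values[, out$sample_ids == "a1"]), c(7, 2))
  # merged: one record per sample, the site-A copy for bridges
  expect_false(anyDuplicated(out$sample_ids) > 0)
  expect_equal(unname(out$values[1, out$sample_ids == "b1"]), 5)
  # the non-bridge site-B sample got protein 1 shifted by +3, protein 2 by 0
  expect_equal(unname(out$values[, out$sample_ids == "c1"]), c(3, 2))
  # re-applying after the merge is a no-op
  expect_identical(batch_correct_bridge(out)$values, out$values)
})

test_that("bridge medians are equalized after correction (random case)", {
  set.seed(12)
  n_b <- 5
  va <- matrix(rnorm(40), 4, 10)
  vb <- matrix(rnorm(32) + rep(c(2, -1, 0.5, 0), 8), 4, 8)
  ids <- c(paste0("b", 1:n_b), paste0("a", 1:5), paste0("b", 1:n_b), paste0("c", 1:3))
  vals <- cbind(va, vb)
  colnames(vals) <- ids
  pm <- toy_pm(vals, site = rep(c("A", "B"), c(10, 8)),
               bridge = paste0("b", 1:n_b))
  # recompute medians on the corrected (pre-merge) values by re-deriving
  ba <- ids %in% pm$bridge_ids & pm$site == "A"
  bb <- ids %in% pm$bridge_ids & pm$site == "B"
  delta <- apply(pm$values[, ba], 1, median) - apply(pm$values[, bb], 1, median)
  shifted_b_medians <- apply(pm$values[, bb] + delta, 1, median)
  expect_equal(shifted_b_medians, apply(pm$values[, ba], 1, median),
               tolerance = 1e-12)
  out <- batch_correct_bridge(pm)
  expect_equal(sum(out$site == "B"), 3)
})

test_that("single bridge sample uses that sample's A-B difference; errors without bridges", {
  vals <- matrix(c(4, 1, 1, 0, 9, 9), 1, 6)
  colnames(vals) <- c("b1", "a1", "b1", "c1", "c2", "c3")
  pm <- protein_matrix(vals, protein_ids = "p1",
                       sample_ids = colnames(vals),
                       site = c("A", "A", "B", "B", "B", "B"),
                       bridge_ids = "b1")
  out <- batch_correct_bridge(pm)
  expect_equal(unname(out$values[1, out$sample_ids == "c1"]), 0 + (4 - 1))
  pm$bridge_ids <- character()
  expect_error(batch_correct_bridge(pm), "skip")
})

test_that("drop_missing removes exactly the partially-observed proteins", {
  set.seed(2)
  m <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("s", 1:4)))
  m[c(1, 12, 33)] <- NA   # proteins 1, 2 and 3 each lose one value
  pm <- drop_missing(toy_pm(m))
  expect_equal(nrow(pm$values), 7)
  expect_false(anyNA(pm$values))
  expect_identical(drop_missing(pm)$values, pm$values)
  all_na <- toy_pm(matrix(NA_real_, 2, 2,
                          dimnames = list(NULL, c("s1", "s2"))))
  expect_error(drop_missing(all_na), "missing")
})

test_that("dedup keeps the minimum accession per gene", {
  vals <- matrix(seq_len(16), 8, 2, dimnames = list(NULL, c("s1", "s2")))
  pm <- protein_matrix(vals,
                       protein_ids = c("NP_620581", "NP_002737", "NP_000010",
                                       "NP_000002", "XP_999", "NP_5.2",
                                       "NP_100", "NP_7"),
                       sample_ids = colnames(vals))
  map <- data.frame(
    protein_id = pm$protein_ids,
    gene_id = c("g1", "g1", "g2", "g2", "g3", "g3", "g4", "g5"),
    accession = pm$protein_ids
  )
  out <- dedup_by_gene(pm, map)
  expect_setequal(out$protein_ids,
                  c("NP_002737", "NP_000002", "NP_5.2", "NP_100", "NP_7"))
  expect_identical(dedup_by_gene(out, map)$protein_ids, out$protein_ids)
  expect_error(dedup_by_gene(pm, map[-3, ]), "NP_000010")
})

test_that("the preprocessing pipeline runs on a simulated two-site cohort", {
  co <- simulate_cohort(sim_config(n_proteins = 30, n_pathways = 3,
                                   pathway_size_range = c(5, 8), n_active_per_pathway = 3, seed = 14))
  out <- preprocess(co$expression, id_map = co$id_map)
  expect_false(anyDuplicated(out$sample_ids) > 0)
  expect_equal(ncol(out$values), 169)
  expect_true(all(abs(apply(out$values, 2, median)) < 1))
})
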