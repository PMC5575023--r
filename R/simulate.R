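# Synthetic two-site proteomics cohort generator: overlapping pathways,
# per-protein site shifts estimated away via bridge samples, and survival
# drawn from a Weibull-baseline Cox model with group-sparse coefficients.
# All draws are governed by cfg$seed plus fixed per-stage offsets, so a
# configuration reproduces its cohort byte for byte.

.SIM_SEED_OFFSETS <- c(pathways = 1L, truth = 2L, expression = 3L,
                       os = 4L, pfs = 5L, clinical = 6L)

#' Simulation configuration
#'
#' Defines the statistical structure of a synthetic cohort. The default
#' sample-site layout follows a two-centre tumour proteomics design: 119 and
#' 82 samples per site with 32 bridge samples measured at both (169 unique
#' patients); times are in months with a Weibull baseline whose median is
#' about 33 months and roughly 30% independent censoring.
#'
#' @param n_site_a,n_site_b Samples measured at site A / site B (bridge
#'   samples count towards both).
#' @param n_bridge Samples measured at both sites (`<= min(n_site_a,
#'   n_site_b)`).
#' @param n_proteins Size of the protein universe.
#' @param n_pathways Number of pathways to plant.
#' @param pathway_size_range Integer pair: smallest and largest pathway size.
#' @param overlap_fraction Target fraction of pathway-assigned proteins
#'   belonging to at least two pathways, in \eqn{[0, 1]}.
#' @param n_active_pathways Pathways carrying survival signal.
#' @param n_active_per_pathway Signal proteins per active pathway
#'   (`<= min(pathway_size_range)`).
#' @param effect_size Magnitude of the non-zero Cox log-hazard coefficients.
#' @param batch_shift_sd SD of the per-protein site-B shift.
#' @param noise_sd SD of the per-record technical measurement noise.
#' @param rho Optional equicorrelation of protein abundances within a
#'   protein's first pathway (default 0 = independent).
#' @param baseline_shape,baseline_scale Weibull baseline hazard parameters
#'   (shape k, scale s): \eqn{T = s(-\log U / e^{x\beta})^{1/k}}.
#' @param censor_rate Target censored fraction in \eqn{[0, 1)}; independent
#'   exponential censoring calibrated by bisection.
#' @param seed Integer seed governing all draws.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_site_a = 119, n_site_b = 82, n_bridge = 32,
                       n_proteins = 100, n_pathways = 10,
                       pathway_size_range = c(8, 12),
                       overlap_fraction = 0.2, n_active_pathways = 2,
                       n_active_per_pathway = 6, effect_size = 1,
                       batch_shift_sd = 0.5, noise_sd = 0.2, rho = 0,
                       baseline_shape = 1.2, baseline_scale = 45,
                       censor_rate = 0.3, seed = 1) {
  cfg <- list(
    n_site_a = as.integer(n_site_a), n_site_b = as.integer(n_site_b),
    n_bridge = as.integer(n_bridge), n_proteins = as.integer(n_proteins),
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    overlap_fraction = overlap_fraction,
    n_active_pathways = as.integer(n_active_pathways),
    n_active_per_pathway = as.integer(n_active_per_pathway),
    effect_size = effect_size, batch_shift_sd = batch_shift_sd,
    noise_sd = noise_sd, rho = rho, baseline_shape = baseline_shape,
    baseline_scale = baseline_scale, censor_rate = censor_rate,
    seed = as.integer(seed)
  )
  if (cfg$n_bridge > min(cfg$n_site_a, cfg$n_site_b)) {
    stop("n_bridge must not exceed min(n_site_a, n_site_b)")
  }
  if (cfg$overlap_fraction < 0 || cfg$overlap_fraction > 1) {
    stop("overlap_fraction must lie in [0, 1]")
  }
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1) {
    stop("censor_rate must lie in [0, 1)")
  }
  if (length(cfg$pathway_size_range) != 2L ||
      cfg$pathway_size_range[1] > cfg$pathway_size_range[2] ||
      cfg$pathway_size_range[1] < 1L) {
    stop("pathway_size_range must be an increasing pair of positive counts")
  }
  if (cfg$n_active_per_pathway > cfg$pathway_size_range[1]) {
    stop("n_active_per_pathway must not exceed min(pathway_size_range)")
  }
  if (cfg$n_active_pathways > cfg$n_pathways) {
    stop("n_active_pathways must not exceed n_pathways")
  }
  if (cfg$batch_shift_sd < 0 || cfg$noise_sd < 0 || cfg$effect_size < 0 ||
      cfg$baseline_shape <= 0 || cfg$baseline_scale <= 0) {
    stop("dispersion, effect and baseline parameters must be non-negative")
  }
  if (is.na(cfg$seed)) stop("an integer seed is mandatory")
  structure(cfg, class = "sim_config")
}

# sample() without the scalar-x surprise
.sample_from <- function(x, size, prob = NULL, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

#' Generate overlapping pathway memberships
#'
#' Draws pathway sizes uniformly from `pathway_size_range`, chooses the
#' number of shared proteins so that the fraction of assigned proteins in at
#' least two pathways matches `overlap_fraction` (shared proteins belong to
#' exactly two pathways), and deals proteins into pathways with
#' capacity-weighted sampling. Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A [pathway_collection()] over the full protein universe.
#' @export
generate_pathways <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + .SIM_SEED_OFFSETS[["pathways"]])
  proteins <- sprintf("P%04d", seq_len(cfg$n_proteins))
  r <- cfg$pathway_size_range
  sizes <- .sample_from(r[1]:r[2], cfg$n_pathways, replace = TRUE)
  slots <- sum(sizes)
  m <- round(cfg$overlap_fraction * slots / (1 + cfg$overlap_fraction))
  n_assigned <- slots - m
  if (slots - 2 * m < 0) {
    stop("infeasible configuration: overlap_fraction too large for the pathway sizes")
  }
  if (n_assigned > cfg$n_proteins) {
    stop("infeasible configuration: pathway sizes cannot be tiled by the protein universe")
  }
  assigned <- .sample_from(proteins, n_assigned)
  mult <- c(rep(2L, m), rep(1L, n_assigned - m))
  for (attempt in seq_len(100L)) {
    cap <- sizes
    members <- replicate(cfg$n_pathways, character(0), simplify = FALSE)
    ok <- TRUE
    for (i in seq_len(n_assigned)) {
      avail <- which(cap > 0)
      if (length(avail) < mult[i]) {
        ok <- FALSE
        break
      }
      pick <- .sample_from(avail, mult[i], prob = cap[avail])
      for (k in pick) members[[k]] <- c(members[[k]], assigned[i])
      cap[pick] <- cap[pick] - 1L
    }
    if (ok) break
  }
  if (!ok) stop("infeasible configuration: could not place overlapping members")
  names(members) <- sprintf("pw%02d", seq_len(cfg$n_pathways))
  pathway_collection(lapply(members, sort), universe = proteins)
}

#' Plant the ground truth of a simulated cohort
#'
#' Chooses the active pathways, draws `n_active_per_pathway` signal proteins
#' within each, assigns them Cox coefficients of magnitude `effect_size`
#' with random signs, and draws per-protein site-B shifts.
#'
#' @param cfg A [sim_config()].
#' @param pathways The [pathway_collection()] from [generate_pathways()].
#' @return An object of class `"ground_truth"`: `true_beta` (named over the
#'   universe), `active_pathways`, `active_proteins`, `site_shift`.
#' @export
generate_truth <- function(cfg, pathways) {
  stopifnot(inherits(cfg, "sim_config"), inherits(pathways, "pathway_collection"))
  set.seed(cfg$seed + .SIM_SEED_OFFSETS[["truth"]])
  universe <- pathways$universe
  active_pw <- sort(.sample_from(names(pathways$sets), cfg$n_active_pathways))
  active <- sort(unique(unlist(lapply(active_pw, function(id) {
    .sample_from(pathways$sets[[id]], cfg$n_active_per_pathway)
  }))))
  beta <- setNames(numeric(length(universe)), universe)
  beta[active] <- cfg$effect_size * .sample_from(c(-1, 1), length(active),
                                                 replace = TRUE)
  shift <- setNames(rnorm(length(universe), 0, cfg$batch_shift_sd), universe)
  structure(list(true_beta = beta, active_pathways = active_pw,
                 active_proteins = active, site_shift = shift),
            class = "ground_truth")
}

#' Generate two-site expression records
#'
#' Draws latent per-sample protein abundances as standard normal log2
#' ratios (optionally equicorrelated within a protein's first pathway via
#' `cfg$rho`), then emits one measurement record per (sample, site) with
#' technical noise of SD `noise_sd`; site-B records additionally carry the
#' per-protein `site_shift`. Bridge samples yield two records. The latent
#' (shift- and noise-free) matrix is attached as attribute `"latent"`.
#'
#' @param cfg A [sim_config()].
#' @param truth A `"ground_truth"` (supplies `site_shift`); pass the
#'   pathways through `pathways` when `cfg$rho > 0`.
#' @param pathways Optional [pathway_collection()], only needed for
#'   correlated abundances.
#' @return A [protein_matrix()] with `n_site_a + n_site_b` records.
#' @export
generate_expression <- function(cfg, truth, pathways = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "ground_truth"))
  if (length(truth$site_shift) != cfg$n_proteins) {
    stop("site_shift length must equal n_proteins")
  }
  set.seed(cfg$seed + .SIM_SEED_OFFSETS[["expression"]])
  proteins <- names(truth$site_shift)
  n_u <- cfg$n_site_a + cfg$n_site_b - cfg$n_bridge
  samples <- sprintf("S%04d", seq_len(n_u))
  bridge <- if (cfg$n_bridge > 0) sort(.sample_from(samples, cfg$n_bridge)) else character(0)
  rest <- setdiff(samples, bridge)
  a_only <- rest[seq_len(cfg$n_site_a - cfg$n_bridge)]
  b_only <- setdiff(rest, a_only)

  z <- matrix(rnorm(cfg$n_proteins * n_u), cfg$n_proteins, n_u,
              dimnames = list(proteins, samples))
  if (cfg$rho > 0) {
    if (is.null(pathways)) stop("correlated abundances need `pathways`")
    fac <- matrix(rnorm(length(pathways$sets) * n_u),
                  length(pathways$sets), n_u)
    first_pw <- rep(NA_integer_, cfg$n_proteins)
    for (k in seq_along(pathways$sets)) {
      idx <- match(pathways$sets[[k]], proteins)
      first_pw[idx[is.na(first_pw[idx])]] <- k
    }
    has <- !is.na(first_pw)
    z[has, ] <- sqrt(1 - cfg$rho) * z[has, , drop = FALSE] +
      sqrt(cfg$rho) * fac[first_pw[has], , drop = FALSE]
  }

  a_samples <- c(bridge, a_only)[order(match(c(bridge, a_only), samples))]
  b_samples <- c(bridge, b_only)[order(match(c(bridge, b_only), samples))]
  noise <- function(k) {
    matrix(rnorm(cfg$n_proteins * k, 0, cfg$noise_sd), cfg$n_proteins, k)
  }
  va <- z[, a_samples, drop = FALSE] + noise(length(a_samples))
  vb <- z[, b_samples, drop = FALSE] + truth$site_shift +
    noise(length(b_samples))
  pm <- protein_matrix(cbind(va, vb), protein_ids = proteins,
                       sample_ids = c(a_samples, b_samples),
                       site = rep(c("A", "B"),
                                  c(length(a_samples), length(b_samples))),
                       bridge_ids = bridge)
  attr(pm, "latent") <- protein_matrix(z, protein_ids = proteins,
                                       sample_ids = samples)
  pm
}

# Exponential censoring rate hit by bisection so that the expected censored
# fraction E[1 - exp(-r T)] matches the target.
.censor_rate_for <- function(t_event, target) {
  f <- function(r) mean(1 - exp(-r * t_event)) - target
  lo <- 1e-12
  hi <- 1
  while (f(hi) < 0 && hi < 1e12) hi <- hi * 10
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Generate survival outcomes from a Cox model
#'
#' Event times follow a Weibull-baseline proportional hazards model,
#' \eqn{T = s(-\log U / e^{x^\top\beta})^{1/k}} (inverse-transform
#' sampling), with independent exponential censoring whose rate is solved by
#' bisection so the expected censored fraction equals `cfg$censor_rate`.
#'
#' @param m A merged [protein_matrix()] (one record per sample); survival is
#'   generated from its values and `truth$true_beta`.
#' @param truth A `"ground_truth"`.
#' @param cfg A [sim_config()].
#' @param endpoint `"os"` or `"pfs"`: separate seeds, and the progression
#'   endpoint uses a baseline scale shrunk to 45% of the survival one so
#'   progression precedes death on average.
#' @return Data frame `sample_id`, `time`, `event`.
#' @export
generate_survival <- function(m, truth, cfg, endpoint = c("os", "pfs")) {
  stopifnot(inherits(m, "protein_matrix"), inherits(truth, "ground_truth"),
            inherits(cfg, "sim_config"))
  endpoint <- match.arg(endpoint)
  if (anyDuplicated(m$sample_ids)) {
    stop("bridge duplicates must be resolved before generating survival")
  }
  set.seed(cfg$seed + .SIM_SEED_OFFSETS[[endpoint]])
  x <- design_matrix(m)
  beta <- truth$true_beta[colnames(x)]
  lp <- drop(x %*% beta)
  scale_ <- cfg$baseline_scale * if (endpoint == "pfs") 0.45 else 1
  u <- runif(nrow(x))
  t_event <- scale_ * (-log(u) / exp(lp))^(1 / cfg$baseline_shape)
  if (cfg$censor_rate == 0) {
    cens <- rep(Inf, length(t_event))
  } else {
    r <- .censor_rate_for(t_event, cfg$censor_rate)
    cens <- rexp(length(t_event), r)
  }
  data.frame(sample_id = m$sample_ids,
             time = pmin(t_event, cens),
             event = as.integer(t_event <= cens),
             stringsAsFactors = FALSE)
}

#' Simulate a complete two-site survival-proteomics cohort
#'
#' Runs [generate_pathways()], [generate_truth()], [generate_expression()]
#' and [generate_survival()] (overall and progression-free survival), and
#' adds outcome-independent clinical covariates (age, stage, tumour
#' residual, platinum status). Survival is generated from the latent
#' (batch- and noise-free) abundances, so the planted signal is biological
#' rather than technical.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `"sim_cohort"`: `config`, `pathways`, `truth`,
#'   `expression` (two-site records), `latent` (noise-free merged matrix),
#'   `clinical` (one row per unique sample) and a 1:1 `id_map`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  pathways <- generate_pathways(cfg)
  truth <- generate_truth(cfg, pathways)
  expr <- generate_expression(cfg, truth, pathways)
  latent <- attr(expr, "latent")
  os <- generate_survival(latent, truth, cfg, "os")
  pfs <- generate_survival(latent, truth, cfg, "pfs")
  set.seed(cfg$seed + .SIM_SEED_OFFSETS[["clinical"]])
  n <- nrow(os)
  clinical <- data.frame(
    sample_id = os$sample_id,
    os_time = os$time, os_event = os$event,
    pfs_time = pfs$time, pfs_event = pfs$event,
    age = round(rnorm(n, 60, 10)),
    stage = .sample_from(1:4, n, prob = c(0.05, 0.10, 0.60, 0.25),
                         replace = TRUE),
    residual = .sample_from(0:3, n, prob = c(0.3, 0.4, 0.15, 0.15),
                            replace = TRUE),
    platinum = rbinom(n, 1, 0.7),
    stringsAsFactors = FALSE
  )
  id_map <- data.frame(protein_id = pathways$universe,
                       gene_id = pathways$universe,
                       accession = pathways$universe,
                       stringsAsFactors = FALSE)
  structure(list(config = cfg, pathways = pathways, truth = truth,
                 expression = expr, latent = latent, clinical = clinical,
                 id_map = id_map),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "simulated cohort: %d unique samples (%d records), %d proteins, %d pathways\n",
    nrow(x$clinical), ncol(x$expression$values),
    x$config$n_proteins, x$config$n_pathways))
  cat(sprintf("  active: %s; %d signal proteins; censored OS fraction %.2f\n",
              paste(x$truth$active_pathways, collapse = ", "),
              length(x$truth$active_proteins),
              mean(x$clinical$os_event == 0)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits `expression.tsv` + `samples.tsv` (see [write_protein_matrix()]),
#' `clinical.tsv`, `pathways.gmt`, `id_map.tsv` and `truth.json`.
#'
#' @param cohort A `"sim_cohort"`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    samples = file.path(dir, "samples.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    gmt = file.path(dir, "pathways.gmt"),
    id_map = file.path(dir, "id_map.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_protein_matrix(cohort$expression, paths["expression"], paths["samples"])
  .write_tsv(cohort$clinical, paths["clinical"])
  write_gmt(cohort$pathways, paths["gmt"])
  .write_tsv(cohort$id_map, paths["id_map"])
  write_json(list(true_beta = as.list(cohort$truth$true_beta),
                  active_pathways = cohort$truth$active_pathways,
                  active_proteins = cohort$truth$active_proteins,
                  site_shift = as.list(cohort$truth$site_shift)),
             paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
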