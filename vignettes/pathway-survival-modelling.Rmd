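---
title: "Pathway-guided survival modelling with the sparse overlapping group lasso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-guided survival modelling with the sparse overlapping group lasso}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soglcox)
```

## The problem

Tumour proteomics cohorts measure thousands of proteins on a few hundred
patients with censored survival outcomes. Selecting prognostic proteins one
at a time ignores that proteins act within biological pathways, and a protein
frequently belongs to several pathways at once. `soglcox` fits a Cox
proportional hazards model whose penalty is structured by pathway membership,
so that selection happens at the level of pathways first and proteins within
them second, while supporting *overlapping* pathways.

## The model

For samples $i = 1, \dots, n$ with failure set $D$ and risk sets
$R_i = \{j : t_j \ge t_i\}$, the fitted objective is

$$
\min_{\tilde v}\;
\frac{1}{n}\sum_{i \in D}\Big[\log \sum_{j \in R_i}
\exp(\tilde X_j \tilde v) - \tilde X_i \tilde v\Big]
+ \lambda\Big[(1-\alpha)\sum_{g \in \varsigma} d_g \lVert \tilde v^g\rVert_2
+ \alpha \lVert \tilde v \rVert_1\Big],
$$

where $\tilde X$ is the *duplicated* design: one column per
(protein, pathway) membership, values copied from the protein's column. A
protein in $k$ pathways appears as $k$ latent copies $\tilde v^g_j$, each
belonging to exactly one group, which turns the overlapping-group penalty
into an ordinary sparse group lasso on $\tilde X$ (the latent-variable
formulation of the overlap norm). The reported protein coefficient collapses
the copies, $\hat\beta_j = \sum_{g \ni j} \hat{\tilde v}^g_j$; a negative
$\hat\beta_j$ means higher expression accompanies longer survival. Groups
with $\lVert \hat{\tilde v}^g \rVert_2 > 0$ are the "dysregulated" pathways;
proteins with $\hat\beta_j \neq 0$ are the "crucial" proteins. Because
collapsing sums copies, a protein whose copies cancel exactly is not
reported as crucial even though its pathways are — the situation is
degenerate and essentially never arises numerically, but it is the defined
behaviour and is unit-tested.

The loss is the standard (Breslow-tied) negative log partial likelihood
scaled by $1/n$. Duplicated columns are centred and scaled to unit variance
before fitting, and all coefficients are reported on that standardized
scale.

### Tunable parameters

* `alpha` (default **0.05**): convex mix between the lasso ($\alpha = 1$)
  and group lasso ($\alpha = 0$) penalties. The small default buys strong
  group-wise sparsity with a little within-group selection.
* `nlambda = 20`, `lambda.min.ratio = 0.1`: a geometric path from
  $\lambda_{\max}$ (smallest penalty with an all-zero fit, computed from the
  null-model gradient through the dual-norm condition and verified by the
  first path entry) down to $0.1\,\lambda_{\max}$.
* `group_weight` (default `"sqrt_size"`): $d_g = \sqrt{|g|}$, the
  conventional group-lasso weight; `"size"` ($d_g = |g|$) is available but
  over-penalizes large pathways. This was a genuinely open design point —
  "group size" is ambiguous between the two — and we default to the
  convention used throughout the group-lasso literature.
* `nfolds = 10`: cross-validation folds, stratified by event status; the
  per-fold score is the Verweij–Van Houwelingen partial-likelihood contrast
  (full-data negative log partial likelihood at the fold-trained
  coefficients minus the training-only value). The selected $\lambda$
  minimizes the mean contrast, ties resolved to the larger $\lambda$.

### Numerical choices

The solver is a monotone accelerated proximal gradient method (FISTA with
backtracking): the penalty's proximal operator is closed-form — elementwise
soft-thresholding at $s\lambda\alpha$ followed by groupwise shrinkage at
$s\lambda(1-\alpha)d_g$, zeroing groups exactly — so each iteration is one
gradient of the partial likelihood plus one prox. Steps that would increase
the objective are rejected and the momentum restarted from the best iterate,
which makes the objective non-increasing by construction. Convergence is
declared when the relative objective change drops below `tol = 1e-8`
(at most `maxit = 10000` iterations, otherwise an error reports the
offending $\lambda$ and gradient norm); the path is solved warm-started from
large to small $\lambda$. $\lambda_{\max}$ is found by per-group bisection
and returned with a $10^{-8}$ relative margin so the first path entry is
exactly zero despite floating-point rounding.

## Choosing the penalty: prediction versus selection

A property worth knowing: the cross-validation *minimum* is a prediction
rule, not a selection rule. On planted-signal simulations the active
pathways enter the path first and are recovered essentially always, but the
CV-minimal $\lambda$ sits deep in the path where additional noise pathways
have entered, because mild overfitting still improves the out-of-fold
partial likelihood. This is the familiar overselection of CV-tuned lasso
methods, and it is visible in `recovery_benchmark()`: pathway recall is
~1.0 while the protein-level false-positive rate at the CV minimum is far
higher than the support of the true signal. Interpreting the selected set
should therefore lean on the ordering in which pathways enter the path and
on the pathway-level scores, not on the raw size of the CV-minimal model. A
one-standard-error-style rule would trade prediction for selection; the
package deliberately implements the plain minimum (with ties to the larger
$\lambda$) as its selection rule and documents the consequence rather than
silently changing the rule.

## Surrounding pipeline

* **Preprocessing** (`preprocess()`): per-sample median re-centering to 0;
  bridge-sample batch correction (site-B values shifted per protein by the
  difference of bridge medians, then bridge duplicates merged keeping the
  site-A record — the larger cohort's laboratory); exclusion of proteins
  with any missing value (no imputation); one protein per gene, keeping the
  minimum accession (numeric part after the prefix, lexicographic
  tie-break). Re-centering is applied before merging the sites; the order
  matters only through the bridge medians, which tolerate missing values.
* **Enrichment** (`enrich_pathways()`, `select_enriched()`): the analysis
  universe is the preprocessed proteins mapping to at least one pathway;
  "hits" default to proteins with univariate Cox Wald $p < 0.05$ (the
  screen is a documented choice — any hit definition can be supplied);
  upper-tail hypergeometric test per pathway, Benjamini–Hochberg across
  pathways, retention at FDR < 0.05. The retained pathways define the
  groups of the SOGL fit.
* **Evaluation**: pathway scores are the latent-coefficient-weighted sums
  of scaled member expression; the time-dependent AUC uses the
  Kaplan–Meier-based cumulative/dynamic estimator (cases are subjects with
  an event by the horizon $t$): sensitivity
  $\{1-\hat S(t\mid X>c)\}\hat P(X>c)/\{1-\hat S(t)\}$ and specificity
  $\hat S(t\mid X\le c)\hat P(X\le c)/\hat S(t)$. This estimator is not
  guaranteed monotone in $c$; the ROC is assembled by walking thresholds
  downwards and applying a cumulative maximum to both coordinates before
  trapezoidal integration (unit-tested, including exact reduction to the
  empirical ROC / Mann–Whitney statistic without censoring). Degenerate
  all-tied markers score 0.5 by convention. Pathway AUC tables are
  in-sample by design (they describe the fitted scores); cross-validated
  AUCs are reported for the final risk scores, where out-of-fold panel
  refitting is well-defined.
* **Risk scores** (`select_predictive_proteins()`, `build_risk_score()`):
  candidates are the crucial proteins; univariate time-dependent AUC is
  computed orientation-free ($\max(a, 1-a)$, since a marker and its
  negation discriminate equally), thresholded at `auc_min` (default 0.90, a
  deliberately stringent bar) and greedily filtered so every retained pair has
  absolute Spearman correlation below `cc_max` (default 0.30; the absolute
  value is the only reading that removes collinearity). Panel weights are
  multivariable Cox coefficients on scaled expression. Risk groups cut the
  score at its 25th/75th percentiles (type-7 linear interpolation, stated
  because the group counts depend on it), compared by Kaplan–Meier curves
  and log-rank tests, and tested for independence from clinical factors by
  univariate-then-multivariate Cox models (factors passing univariate
  $p < 0.05$ enter the multivariable fit; stage and residual are ordinal
  trend codings; the platinum reference level is "resistant").
* **Default horizon**: `horizon_t = 120` time units — ten years when times
  are months, the usual clinical read-out; examples on the synthetic cohort
  use 36 months because its follow-up is calibrated to a ~33-month median.

## What the synthetic generator emulates

`simulate_cohort()` produces the structure the analysis assumes, at desk
scale: two laboratories measuring 119 and 82 samples with 32 bridge samples
measured at both (169 unique patients); latent protein abundances as
standard normal log2 ratios (median-centred data justifies centred
Gaussians; an optional `rho` adds equicorrelation within a protein's first
pathway, default independent — real within-pathway dependence is unknown
and we do not assert it); per-protein site-B shifts of SD `batch_shift_sd
= 0.5` and per-record technical noise of SD `noise_sd = 0.2`; 10
overlapping pathways of 8–12 proteins with 20% of assigned proteins in two
pathways (shared proteins carry multiplicity two, sizes drawn uniformly,
capacity-weighted dealing); 2 active pathways with 6 signal proteins each
at $|\beta| = 1$ with random signs — roughly half a pathway dysregulated, a
deliberately strong but not degenerate signal; survival from a Weibull
baseline ($T = s(-\log U/e^{x\beta})^{1/k}$, closed-form inverse transform;
$k = 1.2$, $s = 45$ months giving a ~33-month baseline median) with
independent exponential censoring whose rate is solved by bisection to hit
the 30% target; progression-free survival uses the same coefficients with
the baseline scale shrunk to 45%. Clinical covariates (age, stage,
residual, platinum) are drawn independently of outcome. Survival is
generated from the *latent* abundances, so the planted signal is biological
rather than technical.

What it does **not** emulate: peptide-level quantification, missing-data
mechanisms correlated with abundance, outcome-associated clinical
covariates, or realistic pathway-size distributions (curated pathway
databases span tens to hundreds of proteins). Passing tests on these cohorts shows
the machinery is correct under its stated assumptions, not that the
defaults reproduce any particular real dataset.

Every generator draw is governed by `seed` plus a fixed per-stage offset,
so a configuration reproduces its cohort byte for byte; `run_pipeline()`
likewise derives its fold seed from the configuration and writes numeric
outputs with a fixed rendering, making identical configurations
byte-identical end to end.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the recovery benchmark at
20 replicates of $n = 200$ with 100 proteins in 10 pathways of 12 (20%
overlap, 2 active pathways, effect 1.0, 30% censoring), and the pipeline
demonstration on the default 169-sample cohort — sizes chosen so the whole
suite exercises every stage in about a minute on one core while keeping the
planted-signal geometry of the full-scale analysis.

## Known limitations

* The CV-minimum overselection described above: pathway recall is excellent,
  protein-level specificity at the CV minimum is not.
* The enrichment gate with few pathways: BH across 10 pathways is
  conservative, and an active pathway can fail FDR < 0.05 on an unlucky
  cohort; the pipeline then proceeds with the pathways that passed.
* In-sample validation figures (pathway AUCs, Table-style hazard ratios of
  a score refit on the same data) are optimistic by construction; the
  cross-validated risk-score AUC is the honest headline number.
* Only the latent/duplication formulation of the overlap penalty is
  provided, matching the analysis it implements; exact overlap-norm solvers
  are out of scope.
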