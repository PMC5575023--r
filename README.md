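# soglcox

Pathway-guided survival modelling for proteomics: a Cox proportional hazards
model penalized with the **sparse overlapping group lasso (SOGL)**, plus the
pipeline around it — two-site batch correction with bridge samples, pathway
enrichment screening, time-dependent ROC/AUC under censoring, and
protein-panel risk scores validated with Kaplan–Meier / log-rank / Cox
analyses.

It is written for analysts of tumour proteomics cohorts (a few hundred
patients, thousands of log2 relative protein abundances, censored overall /
progression-free survival) who want selection structured by pathway
membership rather than protein-by-protein screening, including the common
case where one protein belongs to several pathways.

## The model

With failure set *D*, risk sets *R\_i* = {*j* : *t\_j* ≥ *t\_i*} and a
duplicated design X̃ holding one column per (protein, pathway) membership,
the package solves

```
min over ṽ:  (1/n) Σ_{i∈D} [ log Σ_{j∈R_i} exp(X̃_j ṽ) − X̃_i ṽ ]
             + λ [ (1−α) Σ_g d_g ‖ṽ^g‖₂ + α ‖ṽ‖₁ ]
```

by monotone accelerated proximal gradient descent (the penalty's prox is
closed-form) along a geometric path of 20 λ values from λ\_max down to
0.1·λ\_max, with α = 0.05 and d\_g = √|g| by default. The penalty level is
chosen by 10-fold cross-validation of the Verweij–Van Houwelingen
partial-likelihood contrast. Protein coefficients are the collapsed sums of
their latent copies; pathways with a non-zero latent block are reported as
dysregulated, proteins with non-zero collapsed coefficients as crucial
(negative = higher expression, longer survival).

## Worked example

```r
library(soglcox)

cohort <- simulate_cohort(sim_config(seed = 42))   # two-site synthetic cohort
pm   <- preprocess(cohort$expression, id_map = cohort$id_map)
x    <- design_matrix(pm)
clin <- cohort$clinical[match(rownames(x), cohort$clinical$sample_id), ]

fit <- sogl_cox(x, clin$os_time, clin$os_event, cohort$pathways, seed = 42)
fit
#> Sparse overlapping group lasso Cox model
#>   169 samples (117 events), 84 proteins in 10 pathways (101 latent columns)
#>   alpha = 0.05, path of 20 lambdas in [0.01682, 0.1682]
#>   CV-selected lambda = 0.04435 (index 12 of 20)
#>   selected: 37 proteins, 4 pathways
```

The cohort was simulated with two active pathways (`pw01`, `pw03`); both are
recovered, together with two weakly-weighted extra pathways — the
cross-validated minimum favours prediction over parsimony (see the vignette).
Ranking the selected pathways by 36-month time-dependent AUC puts the planted
ones first:

```r
pathway_auc_table(fit, t = 36)
#>   pathway_id n_nonzero   auc
#> 1       pw01        11 0.831
#> 2       pw03        10 0.804
#> 4       pw09         8 0.690
#> 3       pw05        10 0.629
```

A protein panel is then distilled from the crucial proteins (univariate AUC
above a threshold, pairwise Spearman correlation below 0.30), weighted by
multivariable Cox coefficients, and used to stratify patients:

```r
panel <- select_predictive_proteins(fit$selection$proteins, x,
                                    clin$os_time, clin$os_event,
                                    t = 36, auc_min = 0.6)
rs  <- build_risk_score(panel, x, clin$os_time, clin$os_event)
grp <- risk_groups(attr(rs, "score"))   # low / medium / high at Q25 / Q75
logrank_test(clin$os_time, clin$os_event, grp)
#> log-rank test: chi-square = 117.8682 on 2 df, p = 2.542e-26
```

Higher risk-score tertiles have clearly worse survival; the score itself is
a linear combination of scaled expression, e.g.
`(-0.688 x P0010) + (-0.644 x P0088) + ...`.

The same sequence runs end to end, with TSV/JSON artifacts and a manifest,
via `run_pipeline(pipeline_config(...))`.

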