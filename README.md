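# preemiegut

Longitudinal analysis of gut microbiota succession in preterm infants.

Very-low-birth-weight infants colonise their gut under caesarean delivery,
near-universal antibiotic exposure, and organ immaturity. 16S rRNA
profiling of such cohorts shows a stereotyped succession in which one genus
typically dominates each sample (holding > 50% of reads) and the dominant
organism advances through four phases with postmenstrual age (PMA):
*Staphylococcus* → *Enterococcus* (extremely premature infants only) →
*Enterobacter* → *Bifidobacterium*. `preemiegut` is for microbiome
researchers and neonatologists analysing such longitudinal count data: it
implements the full chain from count-table preprocessing to clinical
statistics, plus a seeded cohort simulator so every stage is testable
without patient data.

## What it computes

* **Preprocessing** — rare-taxon filtering (taxa under 0.001% of total
  reads), relative abundances, per-sample richness, dominance calls
  (strictly > 50% of reads), meconium and contamination flags.
* **Ordination** — Bray-Curtis dissimilarities
  *d(a,b) = Σ|aᵢ−bᵢ| / Σ(aᵢ+bᵢ)*, principal coordinates analysis, and the
  **development index**: the sum of each sample's first two PCoA scores,
  oriented to increase with PMA — a scalar measure of microbiota
  maturation.
* **PERMANOVA** — sequential (Type-I) partitioning of the distance matrix
  over ordered covariates, free or within-infant permutations, exact
  enumeration for small n.
* **Taxon models** — penalized negative-binomial B-spline regression with
  log read-total offset and ridge per-infant intercepts (a tractable
  formulation of the NB GAMM), with deviance-fraction accounting per term.
* **Antibiotic response** — deviations of observed from model-expected
  relative abundance aligned on course start; an infant is a *responder*
  when every deviation in days 1–10 after the course begins is negative.
* **Clinical statistics** — sepsis-window labels (±5 days), abundance
  summaries by window, two-sided Fisher exact tests (probability method)
  for 2×2 cohort tables, exact/approximate rank-sum tests.
* **Simulator** — Dirichlet-multinomial counts over Gaussian-bump
  succession curves on the logit scale, with per-infant random intercepts,
  antibiotic responder mixtures, meconium first samples, and
  hazard-linked sepsis events.

## Worked example

```r
library(preemiegut)

coh <- simulate_cohort(cohort_params(seed = 11))
coh
#> <simulated_cohort> 45 infants, 268 samples, 12 taxa; 50 antibiotic courses, 11 sepsis cases

prop <- relative_abundance(filter_rare(coh$counts))
d    <- bray_curtis(prop)
ord  <- pcoa(d, coh$samples)
ord
#> <pcoa_ordination> 268 samples; 95 positive axes; axis 1-2 explain 74.0%

permanova(d, coh$samples, c("pma_week", "postnatal_day", "birth_mode"),
          permutations = 999, seed = 11)
#> Permutational multivariate ANOVA (999 permutations)
#>           term  df      SS       R2 pseudo_F     p
#>       pma_week   1 17.3781 0.361713  159.164 0.001
#>  postnatal_day   1  1.6243 0.033808   14.877 0.001
#>     birth_mode   1  0.2171 0.004519    1.989 0.136
#>       Residual 264 28.8243 0.599960       NA    NA
```

Postmenstrual age dominates the compositional variation (R² = 0.36 here);
once it is in the model, postnatal age adds little (3%) — the simulated
cohort reproduces the age structure of real preterm succession, where
maturity, not time since birth, drives the community. The development
index correlates with PMA (Spearman ρ = 0.65 on this run), and an
age-adjusted abundance model for the first-phase organism:

```r
fit <- fit_taxon_model(filter_rare(coh$counts), coh$samples,
                       "Staphylococcus", linear_terms = "birth_mode",
                       basis_size = 6)
fit
#> <taxon_model_fit> Staphylococcus: NB(theta=23.7), edf=49.6, deviance explained=65.3%
```

`glance(fit)`, `tidy(fit)`, `autoplot(ord)`, `plot_trend()` and
`plot_deviation_series()` give broom-style summaries and ggplot figures.
`run_pipeline()` chains every stage with TSV handoff and writes a
manifest; `inst/scripts/pipeline.R` wraps it for the shell.

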