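---
title: "Models and methods for longitudinal preterm-infant gut microbiota analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for longitudinal preterm-infant gut microbiota analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preemiegut)
```

## The scientific setting

Very-low-birth-weight infants acquire their gut microbiota under unusual
conditions: caesarean delivery is common, antibiotic exposure is nearly
universal, and the gut itself is developmentally immature. Longitudinal 16S
rRNA profiling of such cohorts shows a highly stereotyped succession in
which a single genus typically holds more than half of the reads in any one
sample, and the identity of that dominant organism advances through four
phases as the infant matures: *Staphylococcus*, then *Enterococcus* (in the
most premature infants only), then *Enterobacter*, and finally
*Bifidobacterium*. The natural clock for this succession is postmenstrual
age (PMA: gestational age at birth plus postnatal age, in weeks) rather
than time since birth.

`preemiegut` implements the full analysis chain for such a cohort:
preprocessing and dominance classification, Bray-Curtis ordination with a
scalar development index, permutational multivariate ANOVA (PERMANOVA),
penalized negative-binomial spline models of single-taxon abundance,
antibiotic responder classification, sepsis-window comparisons, and exact
2×2 cohort statistics — together with a seeded synthetic-cohort simulator,
so that every stage can be exercised and validated without access to
clinical sequence data.

## The synthetic cohort

`simulate_cohort()` generates data with the statistical structure the
downstream analyses assume. Its defaults are the study conditions of a
two-hospital preterm cohort: 21 extremely premature (EP, born before week
28) and 24 moderately/very premature (MVP, week 28 or later) infants, 2–11
stool samples each over postnatal days 0–60, and read depths averaging
about 68,000 (log-normal, capped at 282,000). A term-born comparison group
(`n_term`, sampled over 15 postnatal weeks) is available but defaults to 0,
since the core cohort is the 45 preterm infants.

**Composition curves.** Each taxon's expected abundance follows a Gaussian
bump on the logit scale,
$\ell_t(x) = b_t + a_t \exp\{-(x - p_t)^2 / (2 w_t^2)\} + u_{it}$,
where $x$ is PMA in weeks, $p_t$ the peak week, $w_t$ the width, $a_t$ the
amplitude, and $u_{it} \sim N(0, \sigma_t^2)$ a per-infant random
intercept. Per-sample compositions are the softmax of these logits, so they
always lie on the simplex. A bump was chosen because the observed phases
are described by peaks and declines with no stated functional form; a
smooth unimodal curve is the weakest assumption that reproduces them. The
default peaks are 27.5 weeks (*Staphylococcus*, waning by 35), 30 weeks
(*Enterococcus*), 35 weeks (*Enterobacter*), and a slow rise toward 46
weeks (*Bifidobacterium*, developing after week 30). The *Enterococcus*
amplitude is zeroed outside the EP group, reflecting the observation that
its dominance phase occurs only in extremely premature infants. Subject
standard deviations are largest for *Enterococcus* (1.8) and
*Bifidobacterium* (1.5), where between-infant individuality is reported to
be strongest (roughly 30% and 24% of variation), and small for
*Staphylococcus* (0.6, ~8%); these are qualitative calibrations, not fitted
values. Counts are Dirichlet-multinomial (concentration 30) so replicate
samples are overdispersed relative to multinomial sampling.

**Meconium.** Each infant's first sample is a meconium sample: its depth is
drawn uniformly from [23, 52,000) rather than from the cohort depth law.
The upper bound of 52,000 makes the mean meconium depth about 26,000
reads, matching the reported meconium average, while keeping the minimum at
the reported floor of 23 reads. Its DNA concentration is drawn from a much
lower log-normal, reflecting near-sterile first stool.

**Antibiotics.** Each preterm infant receives an aminoglycoside course with
probability 0.7 (starting days 0–3, the typical empirical regimen at
birth) and vancomycin with probability 0.3 (starting days 7–30). A latent
per-infant, per-drug responder label is drawn with probability
`responder_frac` (default 0.5 per drug, the middle of the reported 37–74%
range). For responders, susceptible taxa are suppressed multiplicatively by
`antibiotic_effect` during days 1–10 after the course start. The
suppression magnitude is a free parameter — no published estimate exists —
and defaults to 0.15, a strong but recoverable knock-down. The vancomycin
susceptibility set deliberately excludes *Enterococcus*: suppressing its
competitors makes its relative abundance *rise* during vancomycin, which
reproduces the reported increasing response of enterococci to that drug
without any additional mechanism.

**Sepsis.** Sepsis is generated as a daily Bernoulli event whose hazard is
`sepsis_rate` times the infant's expected *Staphylococcus* share that day
(default rate 0.02/day, giving on the order of 14 cases per default
cohort). This encodes only the direction of the association — higher
staphylococcal load, higher sepsis risk — not a causal or quantitative
model.

**Determinism.** All randomness derives from one integer seed split into
per-infant streams indexed by (group, within-group index), so removing one
group's infants leaves every other infant's draws untouched.

**What the simulator does not emulate.** Real amplicon data have taxonomic
mis-assignment, compositional artifacts from primer bias, within-day
replicate variation, and antibiotic effects that outlast the course. A
passing pipeline on simulated data therefore demonstrates correctness of
the statistical machinery under the stated generative assumptions, not
performance on real sequencing runs.

## Preprocessing rules

- `filter_rare()` removes taxa whose grand-total count is strictly below
  0.001% of the table total (rare reads are likely errors or chimaeras).
  The threshold is applied to whole-table taxon totals — the stricter
  reading of a "total reads" filter, since a per-sample rule would remove
  more; the comparison carries a 1e-12 relative tolerance so a taxon
  holding exactly the cutoff count is retained on either side of floating
  point. The filter is idempotent.
- `dominant_taxon()` labels a sample only when one taxon holds strictly
  more than 50% of reads; an exact 50/50 split has no dominant.
- `flag_low_read_and_contamination()` marks samples under 100 reads as
  meconium (biologically expected low load, so they are flagged, never
  removed) and compares samples under 1,000 reads against the mean
  negative-control profile, flagging Bray-Curtis dissimilarity below 0.3 as
  control-like. The 0.3 threshold stands in for a judgement originally made
  by visual inspection and is exposed as an argument.
- Day numbering: birth is day 0; "day 1" of an antibiotic course is the
  first full day after the course starts.

## Ordination and PERMANOVA

Bray-Curtis dissimilarity, $d(a,b) = \sum_i |a_i - b_i| / \sum_i (a_i +
b_i)$, feeds classical principal coordinates analysis: double-center
$-d^2/2$, eigendecompose, and scale eigenvectors by the square roots of
positive eigenvalues. Negative eigenvalues are reported but not corrected
(no Cailliez/Lingoes adjustment), as axes beyond the first two are not
interpreted. Eigenvector signs are arbitrary, so the first two axes are
flipped, when needed, to correlate non-negatively (Spearman) with PMA; the
**development index** — the sum of a sample's first two axis scores — then
increases with maturity by construction of the orientation, not of the
ordination itself. Without metadata, the sign convention makes the
largest-magnitude coordinate positive.

`permanova()` performs sequential (Type-I) partitioning of the
Gower-centered distance matrix: per-term sums of squares from incremental
hat-matrix projections, pseudo-F against the full-model residual, and
p-values by freely permuting sample labels, $p = (1 + \#\{F^* \ge F\}) /
(1 + N_{perm})$. Free permutation matches a whole-dataset test; because
repeated measures per infant argue for restricted permutation, a `strata`
argument shuffles only within groups, but it is off by default so the
headline test corresponds to the unrestricted design. `permutations =
"exact"` enumerates all $n!$ orderings for small $n$, which the tests
compare against an independent pairwise-distance enumeration oracle.

## Taxon abundance models

Reported taxon-level associations come from generalized additive mixed
models with a negative-binomial likelihood. `fit_taxon_model()` implements
this as penalized NB regression with log link: cubic B-spline bases
(default dimension 6–8) with a second-difference (P-spline) penalty for
smooth age terms, unpenalized linear/factor terms, ridge-penalized
per-infant intercepts as the subject term, and log total reads as offset so
the mean structure lives on the relative-abundance scale. This replaces
full random-effect integration with a ridge approximation: the mean
structure is identical, and the quantities of interest (deviance fractions
and approximate p-values) are deviance-based, which the ridge fit supports.

Numerical choices: the dispersion is estimated once by method of moments
from the Pearson residuals of an initial Poisson-like fit
($1/\hat\theta = \sum[(y-\hat\mu)^2 - \hat\mu] / \sum \hat\mu^2$, floored
at $10^{-4}$), then held fixed — re-estimating per candidate penalty is
unstable at these sample sizes. Smoothing and ridge penalties are chosen by
minimizing AIC (deviance + 2·edf, edf the trace of the influence matrix)
over a fixed log-spaced grid rather than REML; the grid is coarse by
design, since deviance fractions change slowly in the penalty. The IRLS
working weights are floored at $10^{-8}$ and a tiny ridge is added if the
normal equations are numerically singular (this happens when a spline
region has near-zero fitted counts). In the $\theta \to \infty$ limit with
zero penalty the fit reproduces a Poisson `glm()` to 4 decimals, which the
tests assert.

`variance_explained()` attributes `(dev_reduced − dev_full) /
dev_null` to the terms dropped from the reduced model. The published
"% of variation" does not define its denominator; deviance explained was
chosen and is labeled as such. Sequential attribution over an ordered term
list (`variance_ledger()`) fits the whole model sequence with the
*full-model* dispersion so deviances are comparable; p-values are
likelihood-ratio tests on chi-squared references with effective degrees of
freedom, flagged approximate because penalization shrinks the reference.

Fitted relative abundances are clamped to (0, 1): the NB mean can exceed
the read total on sparse, low-depth samples, but a proportion cannot
exceed one, and downstream deviations must stay in [−1, 1].

## Antibiotic responder analysis

The expected-abundance model deliberately excludes antibiotic covariates,
so the per-sample deviation (observed − expected relative abundance)
isolates the course effect. Deviations are aligned on a day axis re-zeroed
at each course start (samples from −10 to +30 days retained); an infant is
a **responder** for a course when at least one sample falls in days 1–10
after the start and *every* such deviation is strictly negative —
"consistently negative" is read as all-negative, with a zero deviation
counting as non-response, since the contrast class includes "no response".
A course with no in-window samples is undetermined. Samples inside two
overlapping courses contribute to both; per-infant calls take "responder if
any course responds", since published categories are per infant. Responder
fractions are responders over determined infants, with undetermined counts
reported alongside. How infants with multiple courses or no in-window
samples entered the published percentages is not stated; these rules are
the package's explicit substitutes.

`partition_dna()` converts relative abundances into absolute per-taxon DNA
by multiplying each sample's total DNA concentration by its composition;
per-sample sums are conserved exactly.

## Sepsis windows and cohort statistics

Samples within ±5 days of a sepsis diagnosis are "during"; the adjacent
5-day bands are "pre" and "post"; everything else — including every sample
from a never-septic infant — is "none". The band edges are not published
beyond the ±5-day window, so the adjacent-band definition is exposed via
`window_days`. With multiple episodes the nearer diagnosis supplies the
label (an exact pre/post distance tie resolves to "pre"; "during" ties are
only possible between two "during" labels, where the resolution is
immaterial).

`fisher_exact_two_sided()` uses the probability method — summing
hypergeometric probabilities of all margin-compatible tables whose
probability does not exceed the observed table's (relative tolerance
1e-7). The published characteristics table does not name its categorical
test, but the probability-method Fisher test reproduces every printed
p-value, including the telltale p = 1 row, which no asymptotic test
produces. `rank_sum_test()` enumerates all group assignments exactly when
the smaller group has ≤ 8 observations and the enumeration stays under
10^5 assignments, and otherwise uses the tie-corrected normal
approximation without continuity correction.

## Pipeline

`run_pipeline()` executes the stages with plain-TSV handoff, so each stage
is independently testable and any stage's output can be inspected or
regenerated; a JSON manifest records the resolved configuration, package
version, and md5 checksum of every output. A seed is mandatory whenever a
stochastic stage is enabled, and re-running a manifest's configuration
reproduces the run byte-for-byte.

## Problem sizes and validation scale

The package's validation suite exercises: the default 45-infant cohort
(~280 samples) for ordination and the development index; a 60-infant,
~540-sample cohort with subject effects switched off for spline-recovery
checks; a 50-infant densely-sampled cohort for responder-fraction recovery
(recovering a simulated fraction of 0.6 within ±0.15); 500 null
simulations of 20 samples each for PERMANOVA type-I error (rejection rate
at α = 0.05 required to fall in [0.03, 0.07]); 1,000 random 2×2 tables
against a brute-force Fisher oracle; and exhaustive permutation
enumeration at n = 6. These sizes were chosen so each property is tested at
a scale where its failure modes are visible while the full suite stays
quick to run.

## Known limitations

- The ridge-intercept approximation understates between-infant variance
  relative to a true mixed model when infants have very few samples.
- AIC-grid smoothing selection can undersmooth at small n compared with
  REML; the grid bounds are exposed.
- The simulator's antibiotic effect is instantaneous and fully reversible;
  persistent post-course suppression is not modeled.
- Published real-data values (PERMANOVA R² = 0.13 for PMA, per-taxon
  variance fractions, responder percentages) cannot be reproduced here:
  the underlying sequences are not publicly deposited, so the tests verify
  property-based substitutes on simulated cohorts instead.
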