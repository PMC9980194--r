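---
title: "Joint modelling of censored MRD and drug-sensitivity profiles: methods and design"
author: "BayesMRD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of censored MRD and drug-sensitivity profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model and its assumptions

`BayesMRD` fits a single Bayesian posterior over two coupled sub-models.

**Censored autoregressive MRD regression.** Log10 MRD (percent scale) at
day 15 and day 42 of induction, `z^(1)` and `z^(2)`, are normal with
conditional means

```
mu^(1) = beta0^(1) + beta^(1)'X + gamma^(1)'c
mu^(2) = beta0^(2) + delta^(1) * (rho0 + rho z^(1) + beta^(2)'X + gamma^(2)'c)
```

and variances `sigma2^(1)`, `sigma2^(2)`. Observations below the 0.01%
detection limit (`z_low = -2`) enter the likelihood through the normal CDF
term `Phi((z_low - mu)/sigma)`; detected observations through the density.
The day-42 linear predictor is *gated* by the day-15 detection indicator
`delta^(1)`: for a patient already MRD-negative at day 15, day-42 MRD is
modelled as noise around the bare intercept `beta0^(2)`, independent of
covariates, clusters and the AR term. The gate reflects two assumptions
about the data this model targets: censoring is (near-)monotone — day-15
negativity implies day-42 negativity — and the doubly-censored patients
carry essentially no covariate information at day 42, so letting them
inform `beta^(2)` would bias it through the imputation.

**Drug-sensitivity mixture.** The complete (imputed) 5-drug log10 LC50
profile follows a three-component Gaussian mixture with isotropic
per-component covariance `sigma_j^2 I_5`, weights
`w ~ Dirichlet(1/3, 1/3, 1/3)` and means `mu_j ~ N_5(0, I)`. The latent
membership `c_i` (cluster 1 the reference; dummies `(1,0)` and `(0,1)` for
clusters 2 and 3) enters the MRD regression, and its full conditional
multiplies the mixture responsibility by both MRD likelihood blocks — the
two sub-models are estimated *jointly*, so the MRD data can move a patient
whose LC50 profile is ambiguous.

**Priors.** Regression coefficient blocks (`beta^(1)`, `gamma^(1)`,
`beta^(2)`, `gamma^(2)`) carry horseshoe priors: `beta_j ~ N(0,
lambda_j^2 tau^2)` with half-Cauchy(0,1) local scales `lambda_j` (one per
coefficient) and a half-Cauchy(0,1) global scale `tau` per block. The
spike-at-zero/heavy-tail shape performs continuous variable selection:
negligible effects are shrunk hard while genuinely large effects escape.
`rho0, rho ~ N(0,1)`; every variance is Inv-Gamma(3, 2) (mean 1, variance
1 — weakly informative on the standardised scales the model works on).

Two prior choices are the package's own, where the model family leaves them
open. First, the mixture covariance is read as *isotropic per component*
(`sigma_j^2 I_5`, three variance parameters indexed by component): a
diagonal-by-drug alternative (five variances shared across components) is a
defensible alternative reading, but three Inv-Gamma(3,2)-distributed
component variances match the indexing of the stated prior; the isotropic
form is what `mixtureLogLik()` and the sampler implement. Second, the
intercepts `beta0^(t)`, for which no prior is stated by the model family,
get N(0, 10^2) — diffuse on the log10-percent scale where data span roughly
(-2, 2) — so they can absorb the large negative day-42 offset that monotone
censoring implies.

# Estimation

After truncated-normal imputation of the censored MRD values and the
inverse-gamma auxiliary representation of the half-Cauchy scales, every
full conditional is conjugate, so the sampler is a plain Gibbs sweep:

1. censored `z` values: truncated-normal draws below `z_low` given the
   current means and variances (day-15 imputations never feed the day-42
   mean — the gate already zeroes the AR block for those patients);
2. memberships `c_i`: categorical full conditional in log space
   (Gumbel-max), combining mixture weight and density with the day-15 MRD
   density and, when `delta^(1) = 1`, the day-42 density; censored entries
   contribute through their current imputed values, which is
   distributionally equivalent to the CDF form;
3. mixture: `w ~ Dirichlet(alpha + counts)`, conjugate normal means,
   Inv-Gamma variances; empty components are refreshed from the prior;
4. regression, per time point: one joint multivariate-normal draw of
   (intercept, AR terms, covariate and cluster effects) given the horseshoe
   scales, then Inv-Gamma(3 + N/2, 2 + RSS/2) for the variance;
5. horseshoe scales: inverse-gamma auxiliary updates (local scales, their
   auxiliaries, a global scale and its auxiliary, per block).

Defaults follow the intended analysis settings: 15000 iterations, 5000
burn-in, thinning by two (5000 retained draws), a single chain. The run is
fully deterministic given the seed. Initialisation is a warm start chosen
for stability: k-means memberships (k-means++ seeding, multi-restart) on
the standardised LC50 matrix, moment-based mixture parameters, ridge
regression on threshold-imputed responses, all shrinkage scales at one.
The joint log-density is evaluated at every retained draw; a non-finite
value aborts the run with a state dump. Singular regression conditionals
are stabilised by escalating jitter on the Cholesky factor (and logged by
error if even that fails).

A deliberate design decision is the *native* Gibbs sampler rather than
delegation to a probabilistic-programming backend: the joint membership
update — the scientifically interesting coupling — is then an explicit,
unit-testable function (`allocationLogProbs()` is checked against a
brute-force three-term normalisation at 1e-12), and the whole chain stays
seed-reproducible.

# Pre-analysis of the LC50 matrix

Missing LC50 entries (19–40% per drug) are multiply imputed by chained
equations before the joint fit: each sweep regresses every column on all
other current-state columns by Bayesian normal linear regression
(posterior-draw coefficients and residual variance, a 1e-5 ridge and an
IG(0.01, 0.01) variance prior keeping small fixtures proper) and redraws
the column's missing entries from the posterior predictive; ten sweeps,
observed entries untouched. Predictive-mean-matching was deliberately not
used: log10 LC50 values are continuous and unbounded, so the normal model
is the natural conditional. The imputation method sits behind a single
function (`imputeLC50()`) so it can be swapped.

The number of clusters is chosen by the elbow of the total within-cluster
sum of squares: k-means (k-means++ seeding, multi-restart, best WSS kept)
on each completed matrix for k = 1..10, averaged across 100 imputations;
the analysis then fixes k = 3 and uses the completion with the lowest WSS
at k = 3 (ties to the lowest index). Columns are z-scored per drug before
clustering and before the mixture fit — consistent with the N(0, I) prior
on component means — and de-standardised for reporting. Fixing a single
imputation before the joint fit (rather than imputing LC50s inside the
MCMC) is a scope decision with a known cost: posterior uncertainty in
everything downstream of the LC50s is somewhat understated.

# The synthetic-cohort generator

Patient-level data of this kind are not publicly deposited, so the package
ships a generator (`simulateCohort()`) whose defaults emulate the published
cohort-level description, and which returns its generating truth for
recovery testing.

* **Covariates.** Age log-normal (median ~5.4 years, mean ~6.9); gender
  Bernoulli(0.548); log10 WBC normal (median ~16.6 on the raw scale);
  twelve subtype categories with skewed frequencies (ETV6-RUNX1 and
  hyperdiploid 20% each, down to 3.5% for the rarest — all comfortably
  above the 10-patient merging threshold at n = 788); three protocols with
  frequencies 192/788, 428/788, 168/788. Only the summary statistics of
  these marginals are published; the distributional shapes (log-normal age,
  log10-normal WBC) are the generator's own choice of a realistic form.
* **LC50 mixture.** Weights (0.344, 0.339, 0.317); per-drug component
  means forming permutations of (-2, 0, +2) with within-component sd 0.5.
  The permutation design makes every pair of components at least 4 sd apart
  on *every* drug. That strength is not cosmetic: with 19–40% of assays
  missing per drug, a few percent of patients are observed on a single
  drug, and membership recovery (adjusted Rand index >= 0.9 for the Binder
  partition) is only feasible if each drug alone separates the components.
  The implied raw-scale spread (~1.7 log10 units per drug) is on the high
  side of, but within, what ex vivo dilution assays produce. Missingness
  is MCAR per drug at rates (0.19, 0.25, 0.30, 0.35, 0.39) — only rates,
  not a mechanism, are published. Every patient keeps at least one
  observed assay (a patient with none would not be in an LC50 panel).
* **MRD regression truth.** `rho = 1`, `rho0 = 3.8`; three nonzero
  covariate effects (log10 WBC 0.5, hyperdiploid 0.8, T-ALL 0.9), cluster
  contrasts (-0.6, +0.6), all else zero; `sigma2 = 1.2` at both days. The
  intercepts (-2.3 and -6) were calibrated analytically so that ~33% of
  day-15 and ~85% of day-42 values fall below the limit, matching the
  cohort's contingency percentages (verified within the tests to +/- 5
  points over seeds). Monotone censoring is *not* forced structurally: it
  emerges because `beta0^(2) = -6` sits ~3.6 sd below the limit, making a
  day-15-censored, day-42-detected patient a ~1-in-10^4 event — the same
  generative story the model itself tells. A `strictMonotone` flag
  resamples the rare violators below the threshold for tests that require
  exact monotonicity.

What passing recovery tests on these cohorts shows — and does not show:
the generator draws from exactly the fitted model family (normal errors,
MCAR missingness, isotropic mixture), so recovery demonstrates the
estimation machinery is correct and well-calibrated, not that the model is
robust to misspecification (heavy-tailed MRD noise, informative
missingness, non-Gaussian clusters, LC50 values censored at assay
concentration limits are all real-data features the generator does not
emulate).

# Posterior summaries and numerical choices

* Coefficient tables report posterior mean, median and the equal-tailed
  95% interval from empirical type-7 quantiles (the interpolation rule is
  fixed and documented because the selection flag — interval excludes
  zero — must be reproducible to the draw). The AR coefficient is reported
  as median and interquartile range.
* Clustering inference is label-invariant: no online relabelling is done;
  all partition evidence flows through the posterior similarity matrix,
  and the point estimate minimises the equal-cost Binder loss
  `sum_{i<j} |1[c_i = c_j] - psm_ij|`. The search scans candidate
  partitions (the sampled allocation draws, evenly thinned to at most 200)
  and refines the best by greedy single-patient reassignment sweeps that
  always keep one empty cluster on offer, so the refinement can both merge
  and split; ties keep the current assignment, and the result provably
  dominates every scanned draw. Exhaustive enumeration over all set
  partitions validates the optimiser up to n = 8 in the tests.
* Censored-value summaries report the mean of each entry's within-chain
  truncated-normal imputations, which by construction never exceed the
  detection bound; observed values pass through unchanged.
* Convergence diagnostics are split-Rhat and an initial-positive-sequence
  effective sample size, computed natively; constant chains yield NA
  rather than a misleading number, and parameters with Rhat > 1.05 are
  named in a warning.

# Interfaces

The cohort lives in an S4 container extending `SummarizedExperiment`
(patients as columns; the LC50 matrix as the assay; covariates, MRD values
and censoring flags in `colData`), so standard Bioconductor subsetting and
accessor idioms apply. Files use a documented CSV schema: MRD on the
percent scale with a literal `"<0.01"` token for censored entries (numeric
values below the limit are also treated as censored on read), WBC raw,
`lc50_*` columns for the drug panel. On read, Ph-like subtype variants are
merged into one level and subtypes with fewer than 10 patients
(configurable) into `"Other"`. The package's interface is its R functions
— `simulateCohort()`, `imputeLC50()`, `wssCurve()`/`selectImputation()`,
`fitMRDModel()`, the summary functions, and `runPipeline()`, which chains
the stages, derives per-stage seeds from a master seed, and writes all
tabular artifacts plus a manifest (seeds, settings, config hash); these
functions are the command surface, one per pipeline verb.

# Problem sizes used in the shipped checks

The test suite and the acceptance script run at sizes chosen to exercise
every property at desk scale: recovery replicates use n = 800 patients
with 20 imputations, an elbow scan over k = 1..6 and 3000 MCMC iterations
(1000 burn-in, thin 2) — enough for the chain, whose regression and
mixture blocks mix quickly from the warm start, to stabilise interval
estimates; the joint-distribution (Geweke-style) check uses many short
independent successive-conditional chains of 15–20 patients, keeping each
restart's final draw so the kept draws are exactly iid under a correct
kernel; the acceptance script analyses one default cohort of n = 788. The
full-size default MCMC (15000 iterations) behaves identically, only more
slowly.

# Known limitations

* LC50 imputation happens once, before the joint fit; downstream credible
  intervals do not propagate imputation uncertainty.
* The LC50 values themselves are treated as known point estimates;
  censoring of LC50s at the assay's concentration range is not modelled.
* Rare ALL subtypes are pooled into `"Other"` rather than modelled
  hierarchically.
* The AR structure is first order over exactly two time points; more
  serial MRD measures would need a longer gated chain.
* Single-chain defaults mirror the intended analysis; the diagnostics
  accept multiple chains, but the fitting function itself runs one chain
  per call (run it with several seeds for multi-chain Rhat).
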