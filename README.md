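# BayesMRD

Joint Bayesian modelling of serial minimal-residual-disease (MRD)
measurements and *ex vivo* drug-sensitivity profiles in pediatric acute
lymphoblastic leukemia (ALL).

MRD — the fraction of residual leukemic cells in bone marrow — is the key
early marker of treatment response during induction chemotherapy. It is
measured at day 15 and at the end of induction (day 42), with a detection
limit of 0.01%: values below the limit are *left-censored*, not zero. In the
cohorts this package targets, a patient censored at day 15 is essentially
always censored at day 42, so the day-42 measurement carries covariate
information only for patients with detectable day-15 disease. Alongside MRD,
each patient's leukemic cells are assayed *ex vivo* against a panel of five
anti-leukemic drugs (asparaginase, prednisone, vincristine, 6TG, 6MP),
yielding a log10 LC50 profile with substantial missingness (19–40% per
drug). `BayesMRD` is for biostatisticians who want to analyse such data with
a single coherent posterior instead of a chain of ad-hoc steps.

## The model

Let `z_i = (z_i^(1), z_i^(2))` be log10 MRD (percent scale) at days 15 and
42, censored at `z_low = log10(0.01) = -2` with indicators
`delta_i^(t) = 1{z_i^(t) > z_low}`. The likelihood is the standard censored
factorisation — a normal density for detected values, the normal mass below
the limit for censored ones:

    L = prod_t prod_i f(z_i^(t))^delta_i^(t) * F(z_low)^(1 - delta_i^(t))

with conditional means

    mu_i^(1) = beta0^(1) + beta^(1)' X_i + gamma^(1)' c_i
    mu_i^(2) = beta0^(2) + delta_i^(1) * (rho0 + rho z_i^(1)
                                          + beta^(2)' X_i + gamma^(2)' c_i)

so the AR(1) link and all day-42 covariate effects are *gated* on day-15
detectability. `X_i` holds age, gender, log10 WBC, 11 ALL-subtype dummies
(reference ETV6-RUNX1) and 2 protocol dummies (reference T16); `c_i` are
dummies for the patient's latent drug-sensitivity cluster. Regression
coefficients carry horseshoe priors (half-Cauchy local and global scales)
for continuous variable selection; `rho0, rho ~ N(0,1)`; all variances are
Inv-Gamma(3, 2).

The LC50 profiles `Y_i` (after multiple imputation by chained equations, an
elbow scan of k-means within-cluster sums of squares over the imputations,
and selection of the lowest-WSS completion at k = 3) follow a
three-component Gaussian mixture, `sum_j w_j N_5(mu_j, sigma_j^2 I)` with
`w ~ Dirichlet(1/3, 1/3, 1/3)`, `mu_j ~ N_5(0, I)`. The memberships `c_i`
are updated *jointly* with everything else in a native Gibbs sampler whose
allocation full conditional multiplies the mixture terms by both MRD
likelihood blocks; censored MRD values are imputed within the chain by
truncated-normal draws. Clustering is summarised label-invariantly through
the posterior similarity matrix and a Binder-loss partition point estimate;
coefficients are reported with 95% credible intervals and an
interval-excludes-zero selection flag.

A seed-deterministic synthetic-cohort generator
(`cohortSimConfig()`/`simulateCohort()`) reproduces the structure the
analysis assumes — skewed subtype frequencies, three protocols, a separated
LC50 mixture with per-drug missingness, and censored AR MRD pairs
calibrated so roughly 33% of day-15 and 85% of day-42 values fall below the
limit — and returns the generating truth for recovery testing.

## Worked example

```r
library(BayesMRD)

cohort <- simulateCohort(cohortSimConfig(nPatients = 300, seed = 1))
cohort
#> MRDCohort with 300 patients, 5 drugs (assay 'lc50')
#>   censored MRD: day 15 100/300 (33.3%), day 42 246/300 (82.0%)
#>   missing LC50 entries: 29.5%; zLow = -2
#>   subtypes: B-other, DUX4, ETV6-RUNX1, Hyperdiploid, ...

imps <- imputeLC50(cohort, m = 20, seed = 2)
wss  <- wssCurve(imps, kValues = 1:6, seed = 3)
wss                      # elbow at k = 3: 1495 / 720 / 205 / 184 / 168 / 155
sel  <- selectImputation(imps, wss, k = 3)

fit <- fitMRDModel(cohort, Y = imps@completed[[sel]],
                   config = mcmcConfig(nIter = 2000, burnIn = 500,
                                       thin = 2, seed = 4))
fit
#> MRDFit: 750 retained draws (2000 iterations, 500 burn-in, thin 2, seed 4)
#>   rho: posterior median 0.978, IQR 0.884-1.087

coefs <- summarizeCoefficients(fit)
subset(coefs, selected & abs(median) > 0.2)
#>                   parameter median lower95 upper95
#>            day15.Intercept  -2.30   -2.78   -1.88
#>             day15.log10WBC   0.57    0.32    0.83
#>  day15.subtypeHyperdiploid   0.63    0.27    0.99
#>             day15.Cluster2   0.65    0.33    0.99
#>             day15.Cluster3  -0.61   -1.01   -0.00
#>            day42.Intercept  -4.73   -5.73   -4.06
#>                 day42.rho0   2.54    1.66    3.52
#>                  day42.rho   0.98    0.72    1.28

binderPartition(fit)
#> Binder-loss partition: 3 clusters of sizes 113/98/89 (loss 85.65)
```

The day-15 block recovers the generating effects (log10 WBC 0.5,
hyperdiploid 0.8, cluster contrasts ∓0.6); the autoregressive coefficient
posterior (median 0.978) sits on the generating value 1, meaning day-42 MRD
tracks day-15 MRD one-for-one on the log scale for patients with detectable
day-15 disease; truly-zero effects (age, gender, protocol) are shrunk to
negligible medians by the horseshoe. The partition point estimate matches
the generating memberships with adjusted Rand index 0.979 here.

`runPipeline()` chains all of the above (impute → elbow → select → fit →
summarise) and writes every table plus a seed/config manifest to an output
directory; `readCohort()`/`writeCohort()` define the cohort CSV schema
(percent-scale MRD with a `"<0.01"` censoring token, `lc50_*` columns,
automatic merging of rare subtypes).

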