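#' Default ground-truth mixture over log10 LC50 profiles
#'
#' Three well-separated isotropic Gaussian components over the five-drug
#' panel (asparaginase, prednisone, vincristine, 6TG, 6MP), with weights close
#' to the balanced three-way split reported for the fitted partition. Each
#' drug's component means form a permutation of (-2, 0, 2), so every pair of
#' components is separated by at least four within-component standard
#' deviations on every single drug: with 19-40% of assays missing per drug,
#' patients observed on only one or two drugs must still carry cluster
#' information for membership recovery to be feasible.
#'
#' @return list with `w` (3 weights), `mu` (3 x 5 component means), `sigma2`
#'   (3 per-component isotropic variances) and `drugNames`.
#' @export
defaultMixtureTruth <- function() {
  drugs <- c("asparaginase", "prednisone", "vincristine", "6TG", "6MP")
  mu <- rbind(
    c(-2,  -2,   0,   2,   0),
    c( 0,   0,   2,  -2,  -2),
    c( 2,   2,  -2,   0,   2))
  colnames(mu) <- drugs
  list(w = c(0.344, 0.339, 0.317), mu = mu,
       sigma2 = c(0.25, 0.25, 0.25), drugNames = drugs)
}

#' Default ground-truth regression parameters for simulation
#'
#' Sparse day-15 effects (log10 WBC and two subtype dummies nonzero, plus
#' cluster contrasts), a unit autoregressive coefficient, and intercepts
#' calibrated so that roughly a third of day-15 and 85% of day-42 MRD values
#' fall below the 0.01% detection limit. The day-42 intercept sits far below
#' the limit so that the censoring pattern is (near-)monotone: a day-15
#' censored patient is almost surely censored again at day 42.
#'
#' @param xNames design-matrix column names the coefficient vectors refer to.
#' @return list with elements `beta0` (length-2 intercepts), `beta1`, `beta2`
#'   (named covariate effects), `gamma1`, `gamma2` (cluster-2/3 contrasts),
#'   `rho0`, `rho` (AR link), `sigma2` (length-2 observation variances).
#' @export
defaultRegressionTruth <- function(xNames = defaultDesignNames()) {
  beta1 <- setNames(numeric(length(xNames)), xNames)
  beta1["log10WBC"] <- 0.5
  if ("subtypeHyperdiploid" %in% xNames) beta1["subtypeHyperdiploid"] <- 0.8
  if ("subtypeT-ALL" %in% xNames) beta1["subtypeT-ALL"] <- 0.9
  beta2 <- setNames(numeric(length(xNames)), xNames)
  list(beta0 = c(-2.3, -6),
       beta1 = beta1, beta2 = beta2,
       gamma1 = c(-0.6, 0.6), gamma2 = c(0, 0),
       rho0 = 3.8, rho = 1.0,
       sigma2 = c(1.2, 1.2))
}

#' Default subtype vocabulary and design column names
#'
#' Twelve ALL subtype categories with skewed frequencies (ETV6-RUNX1 and
#' hyperdiploid most common, as in childhood ALL), and three treatment
#' protocol labels with skewed frequencies.
#' @return named numeric vector of subtype frequencies.
#' @export
defaultSubtypeFreqs <- function() {
  c("ETV6-RUNX1" = 0.20, "Hyperdiploid" = 0.20, "B-other" = 0.11,
    "T-ALL" = 0.10, "DUX4" = 0.07, "Ph-like" = 0.06, "TCF3-PBX1" = 0.06,
    "KMT2A" = 0.05, "PAX5alt" = 0.04, "Hypodiploid" = 0.035,
    "Ph-positive" = 0.035, "Other" = 0.04)
}

#' @rdname defaultSubtypeFreqs
#' @export
defaultProtocolFreqs <- function() {
  c(T15 = 192, T16 = 428, T17 = 168) / 788
}

#' @rdname defaultSubtypeFreqs
#' @export
defaultDesignNames <- function() {
  subs <- sort(setdiff(names(defaultSubtypeFreqs()), "ETV6-RUNX1"))
  c("age", "Female", "log10WBC", paste0("subtype", subs),
    paste0("protocol", c("T15", "T17")))
}

#' Simulation configuration for synthetic cohorts
#'
#' Bundles every knob of the generator: cohort size, covariate marginals
#' (log-normal age, Bernoulli gender, log10-normal WBC, categorical subtype
#' and protocol), the ground-truth LC50 mixture with per-drug missingness
#' rates, the ground-truth MRD regression, the detection threshold, and the
#' seed. Defaults emulate the overall column of the motivating cohort
#' description (n = 788; 54.8% male; median age about 5.4 years; median WBC
#' about 16.6) and per-drug LC50 missing rates between 19% and 39%.
#'
#' @param nPatients cohort size.
#' @param subtypeFreqs named probabilities over the 12 subtype categories.
#' @param protocolFreqs named probabilities over the 3 protocols.
#' @param maleProb probability of male gender.
#' @param ageLogMean,ageLogSD natural-log scale parameters of age in years.
#' @param wbcLog10Mean,wbcLog10SD log10-scale WBC parameters.
#' @param mixtureTruth see [defaultMixtureTruth()].
#' @param missingRates 5 per-drug missingness probabilities.
#' @param regressionTruth see [defaultRegressionTruth()].
#' @param censorThreshold log10-percent detection limit (default
#'   `log10(0.01) = -2`).
#' @param strictMonotone if `TRUE`, patients censored at day 15 have their
#'   latent day-42 value resampled below the threshold so the censoring
#'   pattern is exactly monotone.
#' @param seed integer master seed.
#' @return validated configuration list of class `SimConfig`.
#' @export
cohortSimConfig <- function(nPatients = 788L,
                            subtypeFreqs = defaultSubtypeFreqs(),
                            protocolFreqs = defaultProtocolFreqs(),
                            maleProb = 0.548,
                            ageLogMean = 1.69, ageLogSD = 0.70,
                            wbcLog10Mean = 1.22, wbcLog10SD = 0.5,
                            mixtureTruth = defaultMixtureTruth(),
                            missingRates = c(0.19, 0.25, 0.30, 0.35, 0.39),
                            regressionTruth = defaultRegressionTruth(),
                            censorThreshold = log10(0.01),
                            strictMonotone = FALSE,
                            seed = 1L) {
  cfg <- list(nPatients = as.integer(nPatients), subtypeFreqs = subtypeFreqs,
              protocolFreqs = protocolFreqs, maleProb = maleProb,
              ageLogMean = ageLogMean, ageLogSD = ageLogSD,
              wbcLog10Mean = wbcLog10Mean, wbcLog10SD = wbcLog10SD,
              mixtureTruth = mixtureTruth, missingRates = missingRates,
              regressionTruth = regressionTruth,
              censorThreshold = censorThreshold,
              strictMonotone = isTRUE(strictMonotone), seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  if (cfg$nPatients < 1L) stop("configuration error: nPatients must be >= 1")
  for (nm in c("subtypeFreqs", "protocolFreqs")) {
    p <- cfg[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
      stop("configuration error: ", nm,
           " must be non-negative and sum to 1 (within 1e-12)")
  }
  if (length(cfg$subtypeFreqs) != 12L)
    stop("configuration error: subtypeFreqs must have 12 categories")
  if (length(cfg$protocolFreqs) != 3L)
    stop("configuration error: protocolFreqs must have 3 categories")
  if (cfg$maleProb < 0 || cfg$maleProb > 1)
    stop("configuration error: maleProb must be a probability")
  if (any(cfg$missingRates < 0) || any(cfg$missingRates > 1))
    stop("configuration error: missingRates must lie in [0, 1]")
  mt <- cfg$mixtureTruth
  if (length(mt$w) != 3L || nrow(mt$mu) != 3L || ncol(mt$mu) != 5L ||
      length(mt$sigma2) != 3L)
    stop("configuration error: mixtureTruth must have 3 components over 5 drugs")
  if (abs(sum(mt$w) - 1) > 1e-12 || any(mt$w < 0))
    stop("configuration error: mixture weights must be a probability vector")
  if (any(mt$sigma2 <= 0))
    stop("configuration error: mixture variances must be positive")
  invisible(TRUE)
}

## Design matrix from a plain covariate data.frame (shared with the
## MRDCohort method, which applies it to colData).
designMatrixFromDF <- function(df) {
  ## keep declared factor levels: a level unobserved in a small cohort still
  ## owns a (all-zero) design column so coefficient vectors keep their shape
  sub <- if (is.factor(df$subtype)) df$subtype else factor(df$subtype)
  prot <- if (is.factor(df$protocol)) df$protocol else factor(df$protocol)
  refSub <- if ("ETV6-RUNX1" %in% levels(sub)) "ETV6-RUNX1" else levels(sub)[1L]
  refProt <- if ("T16" %in% levels(prot)) "T16" else levels(prot)[1L]
  subLev <- sort(setdiff(levels(sub), refSub))
  protLev <- sort(setdiff(levels(prot), refProt))
  X <- cbind(age = df$age, Female = 1 - df$male, log10WBC = df$log10WBC)
  for (s in subLev) X <- cbind(X, as.numeric(sub == s))
  for (p in protLev) X <- cbind(X, as.numeric(prot == p))
  colnames(X) <- c("age", "Female", "log10WBC",
                   paste0("subtype", subLev), paste0("protocol", protLev))
  X
}

#' Simulate baseline covariates
#'
#' Draws age (log-normal, years), gender, log10 WBC (normal) and categorical
#' subtype/protocol labels. Deterministic given `config$seed`.
#'
#' @param config a [cohortSimConfig()] object.
#' @return data.frame with columns `age`, `male`, `log10WBC`, `subtype`,
#'   `protocol`.
#' @export
simulateCovariates <- function(config) {
  validateSimConfig(config)
  set.seed(config$seed)
  n <- config$nPatients
  subNames <- names(config$subtypeFreqs)
  protNames <- names(config$protocolFreqs)
  data.frame(
    age = exp(rnorm(n, config$ageLogMean, config$ageLogSD)),
    male = rbinom(n, 1L, config$maleProb),
    log10WBC = rnorm(n, config$wbcLog10Mean, config$wbcLog10SD),
    subtype = factor(sample(subNames, n, replace = TRUE,
                            prob = config$subtypeFreqs), levels = sort(subNames)),
    protocol = factor(sample(protNames, n, replace = TRUE,
                             prob = config$protocolFreqs),
                      levels = sort(protNames)),
    stringsAsFactors = FALSE)
}

#' Simulate mixture-structured LC50 profiles with missingness
#'
#' Each patient's 5-vector of log10 LC50 values is drawn from the allocated
#' mixture component (isotropic Gaussian), then individual entries are masked
#' missing completely at random at the configured per-drug rates.
#'
#' @param config a [cohortSimConfig()] object.
#' @return list with `lc50` (n x 5 matrix, `NA` = missing) and integer
#'   `allocations` (the ground-truth memberships).
#' @export
simulateLC50 <- function(config) {
  validateSimConfig(config)
  set.seed(config$seed + 1L)
  n <- config$nPatients
  mt <- config$mixtureTruth
  alloc <- sample.int(3L, n, replace = TRUE, prob = mt$w)
  noise <- matrix(rnorm(n * 5L), n, 5L) * sqrt(mt$sigma2[alloc])
  Y <- mt$mu[alloc, , drop = FALSE] + noise
  colnames(Y) <- mt$drugNames
  Yfull <- Y
  for (d in seq_len(5L)) {
    miss <- runif(n) < config$missingRates[d]
    Y[miss, d] <- NA_real_
  }
  ## a patient with no assay at all would not be part of an LC50 panel:
  ## keep one drug observed, chosen with probability proportional to the
  ## per-drug observation rates
  allMiss <- which(rowSums(!is.na(Y)) == 0L)
  for (i in allMiss) {
    d <- sample.int(5L, 1L, prob = 1 - config$missingRates)
    Y[i, d] <- Yfull[i, d]
  }
  list(lc50 = Y, allocations = alloc)
}

#' Simulate censored two-timepoint MRD observations
#'
#' Draws the latent day-15 value from the covariate regression, gates the
#' day-42 autoregressive block on day-15 detectability, censors both values at
#' the detection threshold, and returns the latent (uncensored) values as
#' ground truth. With `strictMonotone = TRUE`, the rare patients who would be
#' detected at day 42 despite a censored day 15 have the latent day-42 value
#' resampled below the threshold.
#'
#' @param covariates data.frame as from [simulateCovariates()].
#' @param allocations integer mixture memberships in `{1, 2, 3}`.
#' @param params regression ground truth ([defaultRegressionTruth()]).
#' @param config a [cohortSimConfig()] object.
#' @return list with `mrd` (data.frame `z1`, `delta1`, `z2`, `delta2`;
#'   censored entries store the bound) and `truth` (latent values,
#'   non-monotone count, parameters, allocations).
#' @export
simulateMRD <- function(covariates, allocations, params, config) {
  validateSimConfig(config)
  set.seed(config$seed + 2L)
  n <- nrow(covariates)
  if (length(allocations) != n)
    stop("shape error: allocations length must equal the number of patients")
  X <- designMatrixFromDF(covariates)
  for (nm in c("beta1", "beta2")) {
    if (length(params[[nm]]) != ncol(X))
      stop("shape error: ", nm, " must have one entry per design column (",
           ncol(X), ")")
  }
  C <- allocationDummies(allocations)
  zlow <- config$censorThreshold
  mu1 <- params$beta0[1L] + drop(X %*% params$beta1) + drop(C %*% params$gamma1)
  z1s <- rnorm(n, mu1, sqrt(params$sigma2[1L]))
  delta1 <- as.integer(z1s > zlow)
  mu2 <- params$beta0[2L] + delta1 *
    (params$rho0 + params$rho * z1s +
       drop(X %*% params$beta2) + drop(C %*% params$gamma2))
  z2s <- rnorm(n, mu2, sqrt(params$sigma2[2L]))
  nonMono <- which(delta1 == 0L & z2s > zlow)
  if (config$strictMonotone && length(nonMono)) {
    z2s[nonMono] <- truncnorm::rtruncnorm(
      length(nonMono), b = zlow, mean = mu2[nonMono],
      sd = sqrt(params$sigma2[2L]))
  }
  delta2 <- as.integer(z2s > zlow)
  mrd <- data.frame(
    z1 = ifelse(delta1 == 1L, z1s, zlow), delta1 = delta1,
    z2 = ifelse(delta2 == 1L, z2s, zlow), delta2 = delta2)
  truth <- list(uncensoredZ = cbind(z1 = z1s, z2 = z2s),
                nonMonotoneCount = if (config$strictMonotone) 0L
                                   else length(nonMono),
                params = params, allocations = allocations)
  list(mrd = mrd, truth = truth)
}

#' Simulate a complete synthetic cohort
#'
#' Composes [simulateCovariates()], [simulateLC50()] and [simulateMRD()] into
#' an [MRDCohort-class]; the ground truth (latent MRD values, allocations,
#' generating parameters) is stored in `metadata(cohort)$truth` for recovery
#' tests. Seed-deterministic: the same configuration always yields the same
#' cohort.
#'
#' @param config a [cohortSimConfig()] object.
#' @return an [MRDCohort-class] with simulation truth in its metadata.
#' @export
simulateCohort <- function(config = cohortSimConfig()) {
  cov <- simulateCovariates(config)
  lc <- simulateLC50(config)
  mrd <- simulateMRD(cov, lc$allocations, config$regressionTruth, config)
  cohort <- MRDCohort(cov, mrd$mrd, lc$lc50, zLow = config$censorThreshold)
  metadata(cohort)$truth <- c(mrd$truth, list(mixture = config$mixtureTruth))
  metadata(cohort)$simConfig <- config
  cohort
}
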