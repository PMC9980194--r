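# Native Gibbs sampler for the joint model. After truncated-normal imputation
# of the censored MRD values and the inverse-gamma augmentation of the
# horseshoe, every full conditional is conjugate; latent cluster memberships
# are drawn from a categorical full conditional that combines the mixture and
# both MRD likelihood blocks.

#' MCMC configuration
#'
#' @param nIter total iterations (default 15000).
#' @param burnIn discarded initial iterations (default 5000).
#' @param thin keep every `thin`-th post-burn-in draw (default 2, so the
#'   defaults retain (15000 - 5000) / 2 = 5000 draws).
#' @param seed integer seed; the run is fully deterministic given it.
#' @return validated list of class `MCMCConfig`.
#' @export
mcmcConfig <- function(nIter = 15000L, burnIn = 5000L, thin = 2L, seed = 1L) {
  cfg <- list(nIter = as.integer(nIter), burnIn = as.integer(burnIn),
              thin = as.integer(thin), seed = as.integer(seed))
  if (cfg$burnIn >= cfg$nIter) stop("burnIn must be smaller than nIter")
  if (cfg$thin < 1L) stop("thin must be at least 1")
  class(cfg) <- "MCMCConfig"
  cfg
}

## Truncated-normal imputation of censored MRD values: draws below the
## detection threshold from the current conditional normal. Day-15 imputations
## never feed the day-42 mean because the AR block is gated off whenever
## delta1 = 0.
updateCensoredMRD <- function(params, X, C, mrd, z1cur, z2cur,
                              zlow = log10(0.01)) {
  s1 <- sqrt(params$sigma2[1L]); s2 <- sqrt(params$sigma2[2L])
  c1 <- which(mrd$delta1 == 0L)
  if (length(c1)) {
    mu1 <- mrdMean(params, X, C, t = 1)
    z1cur[c1] <- truncnorm::rtruncnorm(length(c1), b = zlow,
                                       mean = mu1[c1], sd = s1)
  }
  c2 <- which(mrd$delta2 == 0L)
  if (length(c2)) {
    mu2 <- mrdMean(params, X, C, z1 = mrd$z1, delta1 = mrd$delta1, t = 2)
    z2cur[c2] <- truncnorm::rtruncnorm(length(c2), b = zlow,
                                       mean = mu2[c2], sd = s2)
  }
  list(z1 = z1cur, z2 = z2cur)
}

## Unnormalised log full-conditional of the latent memberships: for each
## patient the three terms combine the mixture weight and density with the
## day-15 MRD density and, for day-15-detected patients, the day-42 density
## (censored entries enter through their current imputed values).
allocationLogProbs <- function(params, mix, X, mrd, z1cur, z2cur, Y) {
  n <- nrow(Y)
  s1 <- sqrt(params$sigma2[1L]); s2 <- sqrt(params$sigma2[2L])
  base1 <- params$beta0[1L] + drop(X %*% params$beta1)
  base2 <- params$beta0[2L] + mrd$delta1 *
    (params$rho0 + params$rho * mrd$z1 + drop(X %*% params$beta2))
  gAdd1 <- c(0, params$gamma1)
  gAdd2 <- c(0, params$gamma2)
  logw <- ifelse(mix$w > 0, log(mix$w), -Inf)
  logp <- matrix(NA_real_, n, 3L)
  for (j in 1:3) {
    s <- sqrt(mix$sigma2[j])
    mixDens <- rowSums(dnorm(Y, rep(mix$mu[j, ], each = n), s, log = TRUE))
    mu1 <- base1 + gAdd1[j]
    mu2 <- base2 + mrd$delta1 * gAdd2[j]
    logp[, j] <- logw[j] + mixDens +
      dnorm(z1cur, mu1, s1, log = TRUE) +
      mrd$delta1 * dnorm(z2cur, mu2, s2, log = TRUE)
  }
  logp
}

## Categorical draw from the allocation full conditional, in log space via
## the Gumbel-max trick.
updateAllocationsDraw <- function(params, mix, X, mrd, z1cur, z2cur, Y) {
  logp <- allocationLogProbs(params, mix, X, mrd, z1cur, z2cur, Y)
  n <- nrow(logp)
  g <- matrix(-log(-log(runif(n * 3L))), n, 3L)
  max.col(logp + g, ties.method = "first")
}

## Conjugate mixture updates; empty components are refreshed from the prior.
updateMixtureDraw <- function(mix, alloc, Y, alpha = 1 / 3) {
  d <- ncol(Y)
  counts <- tabulate(alloc, nbins = 3L)
  w <- rdirichlet1(alpha + counts)
  mu <- mix$mu
  sigma2 <- mix$sigma2
  for (j in 1:3) {
    idx <- which(alloc == j)
    nj <- length(idx)
    if (nj == 0L) {
      mu[j, ] <- rnorm(d)
      sigma2[j] <- rinvgamma(1L, 3, 2)
      next
    }
    Yj <- Y[idx, , drop = FALSE]
    prec <- nj / sigma2[j] + 1
    postMean <- colSums(Yj) / sigma2[j] / prec
    mu[j, ] <- rnorm(d, postMean, sqrt(1 / prec))
    rss <- sum(sweep(Yj, 2L, mu[j, ], "-")^2)
    sigma2[j] <- rinvgamma(1L, 3 + nj * d / 2, 2 + rss / 2)
  }
  list(w = w, mu = mu, sigma2 = sigma2)
}

## Multivariate-normal draw from a conjugate linear-model conditional with
## diagonal prior precision; jitters the precision on Cholesky failure.
drawLinearCoef <- function(W, z, sigma2, priorPrec) {
  A <- crossprod(W) / sigma2 + diag(priorPrec, length(priorPrec))
  b <- crossprod(W, z) / sigma2
  jit <- 0
  repeat {
    R <- tryCatch(chol(A + diag(jit, nrow(A))), error = function(e) NULL)
    if (!is.null(R)) break
    jit <- if (jit == 0) 1e-8 else jit * 10
    if (jit > 1) stop("conditional precision could not be stabilised")
  }
  mean <- backsolve(R, forwardsolve(t(R), b))
  drop(mean + backsolve(R, rnorm(length(b))))
}

## Gibbs draw of the regression block at both time points: coefficients from
## their multivariate-normal conditionals given the horseshoe scales, then
## the observation variances from Inv-Gamma(3 + N/2, 2 + RSS/2).
updateRegressionDraw <- function(params, hs, X, C, mrd, z1cur, z2cur) {
  n <- nrow(X)
  W1 <- cbind(rep(1, n), X, C)
  prior1 <- c(1 / 100,
              1 / (hs$lambda$beta1^2 * hs$tau$beta1^2),
              1 / (hs$lambda$gamma1^2 * hs$tau$gamma1^2))
  b1 <- drawLinearCoef(W1, z1cur, params$sigma2[1L], prior1)
  params$beta0[1L] <- b1[1L]
  params$beta1 <- setNames(b1[2:(1 + ncol(X))], colnames(X))
  params$gamma1 <- b1[(2 + ncol(X)):length(b1)]
  rss1 <- sum((z1cur - drop(W1 %*% b1))^2)
  params$sigma2[1L] <- rinvgamma(1L, 3 + n / 2, 2 + rss1 / 2)

  d1 <- mrd$delta1
  W2 <- cbind(rep(1, n), d1, d1 * mrd$z1, d1 * X, d1 * C)
  prior2 <- c(1 / 100, 1, 1,
              1 / (hs$lambda$beta2^2 * hs$tau$beta2^2),
              1 / (hs$lambda$gamma2^2 * hs$tau$gamma2^2))
  b2 <- drawLinearCoef(W2, z2cur, params$sigma2[2L], prior2)
  params$beta0[2L] <- b2[1L]
  params$rho0 <- b2[2L]
  params$rho <- b2[3L]
  params$beta2 <- setNames(b2[4:(3 + ncol(X))], colnames(X))
  params$gamma2 <- b2[(4 + ncol(X)):length(b2)]
  rss2 <- sum((z2cur - drop(W2 %*% b2))^2)
  params$sigma2[2L] <- rinvgamma(1L, 3 + n / 2, 2 + rss2 / 2)
  params
}

## Horseshoe scale updates via the inverse-gamma auxiliary representation:
## lambda_j^2 | nu_j ~ IG(1, 1/nu_j + beta_j^2 / (2 tau^2)) and so on, one
## local scale per coefficient and one global scale per block.
updateHorseshoeDraw <- function(hs, params) {
  blocks <- list(beta1 = params$beta1, gamma1 = params$gamma1,
                 beta2 = params$beta2, gamma2 = params$gamma2)
  for (b in names(blocks)) {
    beta <- blocks[[b]]
    p <- length(beta)
    lam2 <- rinvgamma(p, 1, 1 / hs$nu[[b]] + beta^2 / (2 * hs$tau[[b]]^2))
    hs$nu[[b]] <- rinvgamma(p, 1, 1 + 1 / lam2)
    tau2 <- rinvgamma(1L, (p + 1) / 2,
                      1 / hs$xi[[b]] + sum(beta^2 / lam2) / 2)
    hs$xi[[b]] <- rinvgamma(1L, 1, 1 + 1 / tau2)
    hs$lambda[[b]] <- sqrt(lam2)
    hs$tau[[b]] <- sqrt(tau2)
  }
  hs
}

## Warm start: k-means memberships, moment-based mixture parameters, ridge
## regression on threshold-imputed responses, unit horseshoe scales.
initSamplerState <- function(X, C0, mrd, Y, zlow) {
  n <- nrow(X)
  km <- kmeansRestart(Y, 3L, nRestarts = 10L)
  alloc <- as.integer(km$cluster)
  counts <- tabulate(alloc, 3L)
  mu <- matrix(0, 3L, ncol(Y))
  sigma2m <- rep(1, 3L)
  for (j in 1:3) {
    if (counts[j] > 0L) {
      Yj <- Y[alloc == j, , drop = FALSE]
      mu[j, ] <- colMeans(Yj)
      if (counts[j] > 1L)
        sigma2m[j] <- max(mean(apply(Yj, 2L, stats::var)), 0.05)
    }
  }
  mix <- list(w = pmax(counts, 0.5) / sum(pmax(counts, 0.5)),
              mu = mu, sigma2 = sigma2m)
  C <- allocationDummies(alloc)
  z1 <- mrd$z1; z2 <- mrd$z2           # censored entries sit at the bound
  ridge <- function(W, z) {
    A <- crossprod(W) + diag(1, ncol(W))
    drop(solve(A, crossprod(W, z)))
  }
  W1 <- cbind(1, X, C)
  b1 <- ridge(W1, z1)
  d1 <- mrd$delta1
  W2 <- cbind(1, d1, d1 * mrd$z1, d1 * X, d1 * C)
  b2 <- ridge(W2, z2)
  params <- list(
    beta0 = c(b1[1L], b2[1L]),
    beta1 = setNames(b1[2:(1 + ncol(X))], colnames(X)),
    gamma1 = b1[(2 + ncol(X)):length(b1)],
    beta2 = setNames(b2[4:(3 + ncol(X))], colnames(X)),
    gamma2 = b2[(4 + ncol(X)):length(b2)],
    rho0 = b2[2L], rho = b2[3L],
    sigma2 = c(max(mean((z1 - drop(W1 %*% b1))^2), 0.1),
               max(mean((z2 - drop(W2 %*% b2))^2), 0.1)))
  ones <- function(p) rep(1, p)
  hs <- list(
    lambda = list(beta1 = ones(ncol(X)), gamma1 = ones(2L),
                  beta2 = ones(ncol(X)), gamma2 = ones(2L)),
    nu = list(beta1 = ones(ncol(X)), gamma1 = ones(2L),
              beta2 = ones(ncol(X)), gamma2 = ones(2L)),
    tau = list(beta1 = 1, gamma1 = 1, beta2 = 1, gamma2 = 1),
    xi = list(beta1 = 1, gamma1 = 1, beta2 = 1, gamma2 = 1))
  list(params = params, hs = hs, mix = mix, alloc = alloc,
       z1 = z1, z2 = z2, kmInit = alloc)
}

#' Fit the joint MRD / drug-sensitivity model by Gibbs sampling
#'
#' Runs the native Gibbs sampler over the joint posterior: truncated-normal
#' imputation of censored MRD values, joint categorical updates of the latent
#' cluster memberships (combining the mixture and both MRD likelihood
#' blocks), conjugate mixture updates, conjugate regression updates under the
#' horseshoe, and inverse-gamma auxiliary updates of the shrinkage scales.
#' Thinned post-burn-in draws are retained. The joint log-density is
#' evaluated at every retained draw and the run aborts if it is ever
#' non-finite.
#'
#' @param cohort an [MRDCohort-class].
#' @param Y complete patients x drugs LC50 matrix (the selected imputation
#'   from [selectImputation()]); if `NULL`, the cohort's own matrix is used
#'   and must be complete.
#' @param config an [mcmcConfig()].
#' @param standardize z-score the LC50 columns before fitting (default
#'   `TRUE`); the standardisation attributes are stored for reporting.
#' @return an [MRDFit-class] object.
#' @export
fitMRDModel <- function(cohort, Y = NULL, config = mcmcConfig(),
                        standardize = TRUE) {
  if (is.null(Y)) Y <- lc50Matrix(cohort)
  Y <- as.matrix(Y)
  if (anyNA(Y))
    stop("Y must be complete; impute missing LC50 values first")
  ctr <- NULL; scl <- NULL
  if (standardize) {
    Y <- standardizeColumns(Y)
    ctr <- attr(Y, "center"); scl <- attr(Y, "scale")
  }
  X <- designMatrix(cohort)
  mrd <- mrdValues(cohort)
  zlow <- zLow(cohort)
  n <- nrow(X)
  set.seed(config$seed)
  st <- initSamplerState(X, NULL, mrd, Y, zlow)

  cens1 <- which(mrd$delta1 == 0L)
  cens2 <- which(mrd$delta2 == 0L)
  nKeep <- (config$nIter - config$burnIn) %/% config$thin
  coefNames1 <- c("Intercept", colnames(X), "Cluster2", "Cluster3")
  coefNames2 <- c("Intercept", "rho0", "rho", colnames(X),
                  "Cluster2", "Cluster3")
  draws <- list(
    coefficients1 = matrix(NA_real_, nKeep, length(coefNames1),
                           dimnames = list(NULL, coefNames1)),
    coefficients2 = matrix(NA_real_, nKeep, length(coefNames2),
                           dimnames = list(NULL, coefNames2)),
    sigma2 = matrix(NA_real_, nKeep, 2L,
                    dimnames = list(NULL, c("sigma2_1", "sigma2_2"))),
    mixtureWeights = matrix(NA_real_, nKeep, 3L,
                            dimnames = list(NULL, paste0("w", 1:3))),
    mixtureMeans = matrix(NA_real_, nKeep, 3L * ncol(Y),
                          dimnames = list(NULL, paste0(
                            rep(colnames(Y), each = 3L), ".comp", 1:3))),
    mixtureVars = matrix(NA_real_, nKeep, 3L,
                         dimnames = list(NULL, paste0("sigma2_comp", 1:3))),
    hsTau = matrix(NA_real_, nKeep, 4L,
                   dimnames = list(NULL, c("tau_beta1", "tau_gamma1",
                                           "tau_beta2", "tau_gamma2"))),
    logJoint = matrix(NA_real_, nKeep, 1L,
                      dimnames = list(NULL, "logJoint")),
    imputedZ1 = matrix(NA_real_, nKeep, length(cens1),
                       dimnames = list(NULL, rownames(X)[cens1])),
    imputedZ2 = matrix(NA_real_, nKeep, length(cens2),
                       dimnames = list(NULL, rownames(X)[cens2])))
  allocDraws <- matrix(NA_integer_, nKeep, n,
                       dimnames = list(NULL, rownames(X)))

  keep <- 0L
  C <- allocationDummies(st$alloc)
  for (iter in seq_len(config$nIter)) {
    zz <- updateCensoredMRD(st$params, X, C, mrd, st$z1, st$z2, zlow)
    st$z1 <- zz$z1; st$z2 <- zz$z2
    st$alloc <- updateAllocationsDraw(st$params, st$mix, X, mrd,
                                      st$z1, st$z2, Y)
    C <- allocationDummies(st$alloc)
    st$mix <- updateMixtureDraw(st$mix, st$alloc, Y)
    st$params <- updateRegressionDraw(st$params, st$hs, X, C, mrd,
                                      st$z1, st$z2)
    st$hs <- updateHorseshoeDraw(st$hs, st$params)

    if (iter > config$burnIn &&
        (iter - config$burnIn) %% config$thin == 0L) {
      keep <- keep + 1L
      p <- st$params
      draws$coefficients1[keep, ] <- c(p$beta0[1L], p$beta1, p$gamma1)
      draws$coefficients2[keep, ] <- c(p$beta0[2L], p$rho0, p$rho,
                                       p$beta2, p$gamma2)
      draws$sigma2[keep, ] <- p$sigma2
      draws$mixtureWeights[keep, ] <- st$mix$w
      draws$mixtureMeans[keep, ] <- as.vector(st$mix$mu)
      draws$mixtureVars[keep, ] <- st$mix$sigma2
      draws$hsTau[keep, ] <- unlist(st$hs$tau)
      draws$imputedZ1[keep, ] <- st$z1[cens1]
      draws$imputedZ2[keep, ] <- st$z2[cens2]
      allocDraws[keep, ] <- st$alloc
      lj <- logJointDensity(list(params = p, hs = st$hs, mix = st$mix,
                                 alloc = st$alloc),
                            X, C, mrd, Y, zlow)
      if (!is.finite(lj))
        stop("non-finite joint log-density at iteration ", iter,
             "; sigma2 = ", paste(signif(p$sigma2, 4), collapse = ", "),
             "; mixture weights = ",
             paste(signif(st$mix$w, 4), collapse = ", "))
      draws$logJoint[keep, ] <- lj
    }
  }
  new("MRDFit", draws = draws, allocations = allocDraws,
      config = unclass(config),
      dataInfo = list(nPatients = n, censoredDay15 = cens1,
                      censoredDay42 = cens2, zLow = zlow,
                      drugNames = colnames(Y),
                      lc50Center = ctr, lc50Scale = scl,
                      coefNames1 = coefNames1, coefNames2 = coefNames2,
                      kmeansInit = st$kmInit))
}

#' Access retained posterior draws
#'
#' @param fit an [MRDFit-class].
#' @param block one of `"coefficients1"`, `"coefficients2"`, `"sigma2"`,
#'   `"mixtureWeights"`, `"mixtureMeans"`, `"mixtureVars"`, `"hsTau"`,
#'   `"logJoint"`, `"imputedZ1"`, `"imputedZ2"`, `"allocations"`.
#' @return matrix of draws (rows) by components (columns).
#' @export
setGeneric("posteriorDraws", function(fit, block) {
  standardGeneric("posteriorDraws")
})

#' @rdname posteriorDraws
#' @export
setMethod("posteriorDraws", "MRDFit", function(fit, block) {
  if (block == "allocations") return(fit@allocations)
  if (!block %in% names(fit@draws))
    stop("unknown draw block: ", block)
  fit@draws[[block]]
})

#' @describeIn fitMRDModel number of retained draws.
#' @param fit an `MRDFit`.
#' @export
nDraws <- function(fit) nrow(fit@allocations)

#' @describeIn fitMRDModel compact display of a fitted model.
#' @param object an `MRDFit`.
#' @export
setMethod("show", "MRDFit", function(object) {
  cfg <- object@config
  cat("MRDFit:", nrow(object@allocations), "retained draws",
      sprintf("(%d iterations, %d burn-in, thin %d, seed %d)\n",
              cfg$nIter, cfg$burnIn, cfg$thin, cfg$seed))
  rho <- object@draws$coefficients2[, "rho"]
  cat(sprintf("  rho: posterior median %.3f, IQR %.3f-%.3f\n",
              median(rho), quantile(rho, 0.25), quantile(rho, 0.75)))
  sizes <- tabulate(object@allocations[nrow(object@allocations), ], 3L)
  cat("  last-draw cluster sizes:", paste(sizes, collapse = "/"), "\n")
})
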