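# Shared fixtures and independent oracles used across the suite.

## Small synthetic cohort for fast end-to-end checks.
smallConfig <- function(n = 80L, seed = 1L, ...) {
  cohortSimConfig(nPatients = n, seed = seed, ...)
}

## All set partitions of 1..n as a matrix of label vectors (one per row),
## labels contiguous in order of first appearance. Independent enumeration
## oracle for the Binder-loss minimiser.
allPartitions <- function(n) {
  parts <- list(c(1L))
  for (i in 2L:n) {
    parts <- unlist(lapply(parts, function(p) {
      k <- max(p)
      lapply(seq_len(k + 1L), function(g) c(p, g))
    }), recursive = FALSE)
  }
  do.call(rbind, parts)
}

## Rejection sampler for a normal truncated above at b: the oracle the
## sampler's truncated draws are compared against.
rejectionTruncNorm <- function(n, mean, sd, b) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * n, mean, sd)
    out <- c(out, x[x <= b])
  }
  out[seq_len(n)]
}

## Brute-force Binder loss (direct double loop definition).
bruteBinderLoss <- function(labels, psm) {
  n <- length(labels)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      tot <- tot + abs(as.numeric(labels[i] == labels[j]) - psm[i, j])
    }
  }
  tot
}

## Successive-conditional (Geweke-style) simulation as many short
## independent chains. Each restart draws all parameters from their priors,
## then alternates data regeneration with one full Gibbs sweep for `length`
## cycles; the final draws across restarts are exactly iid from the prior
## when every update is correct. Horseshoe scales are held at `hs` (pinned)
## so the regression-coefficient prior is the same on both sides.
gewekeRestarts <- function(X, hs, nRestarts, length, zlow = -2) {
  n <- nrow(X)
  p <- ncol(X)
  rho <- sigma2 <- w1 <- numeric(nRestarts)
  for (r in seq_len(nRestarts)) {
    par <- list(beta0 = rnorm(2L, 0, 10),
                beta1 = setNames(rnorm(p), colnames(X)),
                beta2 = setNames(rnorm(p), colnames(X)),
                gamma1 = rnorm(2L), gamma2 = rnorm(2L),
                rho0 = rnorm(1L), rho = rnorm(1L),
                sigma2 = 1 / rgamma(2L, 3, rate = 2))
    mix <- list(w = BayesMRD:::rdirichlet1(rep(1 / 3, 3L)),
                mu = matrix(rnorm(15L), 3L, 5L),
                sigma2 = 1 / rgamma(3L, 3, rate = 2))
    for (it in seq_len(length)) {
      alloc <- sample.int(3L, n, replace = TRUE, prob = mix$w)
      Y <- mix$mu[alloc, , drop = FALSE] +
        matrix(rnorm(n * 5L), n, 5L) * sqrt(mix$sigma2[alloc])
      C <- BayesMRD:::allocationDummies(alloc)
      z1s <- rnorm(n, mrdMean(par, X, C, t = 1), sqrt(par$sigma2[1L]))
      d1 <- as.integer(z1s > zlow)
      z2s <- rnorm(n, mrdMean(par, X, C, z1 = z1s, delta1 = d1, t = 2),
                   sqrt(par$sigma2[2L]))
      d2 <- as.integer(z2s > zlow)
      mrd <- data.frame(z1 = ifelse(d1 == 1L, z1s, zlow), delta1 = d1,
                        z2 = ifelse(d2 == 1L, z2s, zlow), delta2 = d2)
      zz <- BayesMRD:::updateCensoredMRD(par, X, C, mrd,
                                         mrd$z1, mrd$z2, zlow)
      al <- BayesMRD:::updateAllocationsDraw(par, mix, X, mrd,
                                             zz$z1, zz$z2, Y)
      C <- BayesMRD:::allocationDummies(al)
      mix <- BayesMRD:::updateMixtureDraw(mix, al, Y)
      par <- BayesMRD:::updateRegressionDraw(par, hs, X, C, mrd,
                                             zz$z1, zz$z2)
    }
    rho[r] <- par$rho
    sigma2[r] <- par$sigma2[1L]
    w1[r] <- mix$w[1L]
  }
  list(rho = rho, sigma2 = sigma2, w1 = w1)
}

## Minimal hand-built MRDFit for summary-level tests: draws supplied
## directly, two censored patients per time point.
makeManualFit <- function(coef1, coef2, sigma2, alloc,
                          imputedZ1 = NULL, imputedZ2 = NULL,
                          cens1 = integer(0), cens2 = integer(0)) {
  nd <- nrow(coef1)
  blank <- function(m) matrix(0, nd, m)
  if (is.null(imputedZ1)) imputedZ1 <- matrix(0, nd, length(cens1))
  if (is.null(imputedZ2)) imputedZ2 <- matrix(0, nd, length(cens2))
  draws <- list(
    coefficients1 = coef1, coefficients2 = coef2, sigma2 = sigma2,
    mixtureWeights = blank(3L), mixtureMeans = blank(15L),
    mixtureVars = blank(3L) + 1, hsTau = blank(4L) + 1,
    logJoint = blank(1L), imputedZ1 = imputedZ1, imputedZ2 = imputedZ2)
  new("MRDFit", draws = draws, allocations = alloc,
      config = list(nIter = nd, burnIn = 0L, thin = 1L, seed = 1L),
      dataInfo = list(nPatients = ncol(alloc), censoredDay15 = cens1,
                      censoredDay42 = cens2, zLow = -2))
}
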