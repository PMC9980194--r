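# Unit tests of the individual Gibbs updates plus whole-chain contracts.

## shared tiny data setup: p design columns, mixed censoring
samplerFixture <- function(n = 30L, p = 3L, seed = 31L) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  alloc <- sample.int(3L, n, replace = TRUE)
  C <- BayesMRD:::allocationDummies(alloc)
  params <- list(beta0 = c(-1, -4),
                 beta1 = setNames(c(0.5, rep(0, p - 1L)), colnames(X)),
                 beta2 = setNames(rep(0, p), colnames(X)),
                 gamma1 = c(-0.5, 0.5), gamma2 = c(0, 0),
                 rho0 = 2, rho = 1, sigma2 = c(1, 1))
  z1s <- rnorm(n, mrdMean(params, X, C, t = 1), 1)
  d1 <- as.integer(z1s > -2)
  z2s <- rnorm(n, mrdMean(params, X, C, z1 = z1s, delta1 = d1, t = 2), 1)
  d2 <- as.integer(z2s > -2)
  mrd <- data.frame(z1 = ifelse(d1 == 1L, z1s, -2), delta1 = d1,
                    z2 = ifelse(d2 == 1L, z2s, -2), delta2 = d2)
  Y <- matrix(rnorm(n * 5L), n, 5L,
              dimnames = list(NULL, paste0("d", 1:5)))
  mix <- list(w = c(0.4, 0.35, 0.25), mu = matrix(rnorm(15), 3L, 5L),
              sigma2 = c(0.8, 1, 1.2))
  list(X = X, C = C, alloc = alloc, params = params, mrd = mrd,
       Y = Y, mix = mix)
}

test_that("censored-value imputation stays below the bound with the right law", {
  n <- 20000L
  X <- matrix(0, n, 1L)
  C <- BayesMRD:::allocationDummies(rep(1L, n))
  params <- list(beta0 = c(-2, -2), beta1 = c(x1 = 0), beta2 = c(x1 = 0),
                 gamma1 = c(0, 0), gamma2 = c(0, 0), rho0 = 0, rho = 0,
                 sigma2 = c(1, 1))
  mrd <- data.frame(z1 = rep(-2, n), delta1 = 0L,
                    z2 = rep(0.5, n), delta2 = 1L)
  set.seed(41)
  draws <- numeric(0)
  for (r in 1:5) {
    zz <- BayesMRD:::updateCensoredMRD(params, X, C, mrd,
                                       mrd$z1, mrd$z2, zlow = -2)
    draws <- c(draws, zz$z1)
    expect_true(all(zz$z1 <= -2))
    expect_identical(zz$z2, mrd$z2)   # observed day-42 untouched
  }
  # truncated-normal moment: mean = mu - phi(0)/Phi(0) when mu = zlow
  expect_lt(abs(mean(draws) - (-2 - sqrt(2 / pi))), 0.01)
})

test_that("truncated draws match a rejection-sampling oracle (KS)", {
  n <- 10000L
  X <- matrix(0, n, 1L)
  C <- BayesMRD:::allocationDummies(rep(1L, n))
  params <- list(beta0 = c(-1, -1), beta1 = c(x1 = 0), beta2 = c(x1 = 0),
                 gamma1 = c(0, 0), gamma2 = c(0, 0), rho0 = 0, rho = 0,
                 sigma2 = c(1.44, 1))
  mrd <- data.frame(z1 = rep(-2, n), delta1 = 0L,
                    z2 = rep(0.5, n), delta2 = 1L)
  set.seed(42)
  zz <- BayesMRD:::updateCensoredMRD(params, X, C, mrd, mrd$z1, mrd$z2,
                                     zlow = -2)
  oracle <- rejectionTruncNorm(n, mean = -1, sd = 1.2, b = -2)
  ks <- suppressWarnings(stats::ks.test(zz$z1, oracle))
  expect_gt(ks$p.value, 0.01)
})

test_that("allocation full conditional matches brute-force normalisation", {
  fx <- samplerFixture()
  # gamma = 0: reduces to the mixture-only responsibility
  p0 <- fx$params; p0$gamma1 <- c(0, 0); p0$gamma2 <- c(0, 0)
  lp <- BayesMRD:::allocationLogProbs(p0, fx$mix, fx$X, fx$mrd,
                                      fx$mrd$z1, fx$mrd$z2, fx$Y)
  probs <- exp(lp - apply(lp, 1L, max))
  probs <- probs / rowSums(probs)
  for (i in seq_len(nrow(fx$Y))) {
    terms <- vapply(1:3, function(j) {
      fx$mix$w[j] * prod(dnorm(fx$Y[i, ], fx$mix$mu[j, ],
                               sqrt(fx$mix$sigma2[j])))
    }, numeric(1))
    expect_equal(probs[i, ], terms / sum(terms), tolerance = 1e-12)
  }

  # full conditional with gamma active: independent 3-term oracle
  lp <- BayesMRD:::allocationLogProbs(fx$params, fx$mix, fx$X, fx$mrd,
                                      fx$mrd$z1, fx$mrd$z2, fx$Y)
  probs <- exp(lp - apply(lp, 1L, max))
  probs <- probs / rowSums(probs)
  p <- fx$params
  for (i in seq_len(5L)) {
    terms <- vapply(1:3, function(j) {
      g1 <- c(0, p$gamma1)[j]; g2 <- c(0, p$gamma2)[j]
      mu1 <- p$beta0[1L] + sum(fx$X[i, ] * p$beta1) + g1
      t1 <- dnorm(fx$mrd$z1[i], mu1, sqrt(p$sigma2[1L]))
      t2 <- 1
      if (fx$mrd$delta1[i] == 1L) {
        mu2 <- p$beta0[2L] + p$rho0 + p$rho * fx$mrd$z1[i] +
          sum(fx$X[i, ] * p$beta2) + g2
        t2 <- dnorm(fx$mrd$z2[i], mu2, sqrt(p$sigma2[2L]))
      }
      fx$mix$w[j] * prod(dnorm(fx$Y[i, ], fx$mix$mu[j, ],
                               sqrt(fx$mix$sigma2[j]))) * t1 * t2
    }, numeric(1))
    expect_equal(probs[i, ], terms / sum(terms), tolerance = 1e-12)
  }
})

test_that("identical components with zero gamma give the weights back", {
  fx <- samplerFixture()
  p0 <- fx$params; p0$gamma1 <- c(0, 0); p0$gamma2 <- c(0, 0)
  mixSame <- list(w = c(0.5, 0.3, 0.2), mu = matrix(0.1, 3L, 5L),
                  sigma2 = rep(1, 3L))
  lp <- BayesMRD:::allocationLogProbs(p0, mixSame, fx$X, fx$mrd,
                                      fx$mrd$z1, fx$mrd$z2, fx$Y)
  probs <- exp(lp - apply(lp, 1L, max)); probs <- probs / rowSums(probs)
  for (i in seq_len(nrow(probs)))
    expect_equal(probs[i, ], mixSame$w, tolerance = 1e-12)
})

test_that("a strong MRD signal overrides an ambiguous LC50 profile", {
  # patient equidistant between components 1 and 2 in LC50 space
  X <- matrix(0, 1L, 1L)
  mix <- list(w = c(0.5, 0.5, 0), mu = rbind(rep(-1, 5), rep(1, 5), 0),
              sigma2 = rep(1, 3L))
  Y <- matrix(0, 1L, 5L)
  params <- list(beta0 = c(0, -4), beta1 = c(x1 = 0), beta2 = c(x1 = 0),
                 gamma1 = c(50, 0), gamma2 = c(0, 0), rho0 = 0, rho = 0,
                 sigma2 = c(1, 1))
  mrd <- data.frame(z1 = 50, delta1 = 1L, z2 = 0.5, delta2 = 1L)
  lp <- BayesMRD:::allocationLogProbs(params, mix, X, mrd,
                                      mrd$z1, mrd$z2, Y)
  probs <- exp(lp - max(lp)); probs <- probs / sum(probs)
  expect_gt(probs[1L, 2L], 0.999)
  # hand check: the two log-terms differ only by the day-15 density
  expect_equal(lp[1L, 2L] - lp[1L, 1L],
               dnorm(50, 50, 1, log = TRUE) - dnorm(50, 0, 1, log = TRUE),
               tolerance = 1e-10)
})

test_that("regression update approaches OLS in the flat-prior limit", {
  set.seed(44)
  n <- 150L
  X <- matrix(rnorm(n * 3L), n, 3L,
              dimnames = list(NULL, paste0("x", 1:3)))
  alloc <- sample.int(3L, n, replace = TRUE)
  C <- BayesMRD:::allocationDummies(alloc)
  z1 <- rnorm(n, 1 + X %*% c(0.8, -0.5, 0.3) + C %*% c(0.4, -0.4), 0.7)
  z2 <- rnorm(n, 0.5 + 0.9 * z1, 0.7)
  mrd <- data.frame(z1 = z1, delta1 = 1L, z2 = z2, delta2 = 1L)
  params <- list(beta0 = c(0, 0), beta1 = setNames(rep(0, 3L), colnames(X)),
                 beta2 = setNames(rep(0, 3L), colnames(X)),
                 gamma1 = c(0, 0), gamma2 = c(0, 0), rho0 = 0, rho = 0,
                 sigma2 = c(1, 1))
  hs <- list(lambda = list(beta1 = rep(1e4, 3L), gamma1 = rep(1e4, 2L),
                           beta2 = rep(1e4, 3L), gamma2 = rep(1e4, 2L)),
             tau = list(beta1 = 1, gamma1 = 1, beta2 = 1, gamma2 = 1))
  acc <- matrix(0, 400L, 3L)
  for (r in seq_len(400L)) {
    draw <- BayesMRD:::updateRegressionDraw(params, hs, X, C, mrd, z1, z2)
    acc[r, ] <- draw$beta1
  }
  ols <- coef(lm(z1 ~ X + C))[2:4]
  expect_equal(unname(colMeans(acc)), unname(ols), tolerance = 0.05)
})

test_that("with no data the regression update samples the prior", {
  X <- matrix(0, 0L, 2L, dimnames = list(NULL, c("x1", "x2")))
  C <- matrix(0, 0L, 2L)
  mrd <- data.frame(z1 = numeric(0), delta1 = integer(0),
                    z2 = numeric(0), delta2 = integer(0))
  params <- list(beta0 = c(0, 0), beta1 = c(x1 = 0, x2 = 0),
                 beta2 = c(x1 = 0, x2 = 0), gamma1 = c(0, 0),
                 gamma2 = c(0, 0), rho0 = 0, rho = 0, sigma2 = c(1, 1))
  hs <- list(lambda = list(beta1 = rep(1, 2L), gamma1 = rep(1, 2L),
                           beta2 = rep(1, 2L), gamma2 = rep(1, 2L)),
             tau = list(beta1 = 1, gamma1 = 1, beta2 = 1, gamma2 = 1))
  set.seed(45)
  nDr <- 10000L
  s2 <- b0 <- b1 <- r0 <- numeric(nDr)
  for (r in seq_len(nDr)) {
    d <- BayesMRD:::updateRegressionDraw(params, hs, X, C, mrd,
                                         numeric(0), numeric(0))
    s2[r] <- d$sigma2[1L]; b0[r] <- d$beta0[1L]
    b1[r] <- d$beta1[1L]; r0[r] <- d$rho0
  }
  expect_lt(abs(mean(s2) - 1), 0.05)        # IG(3,2) mean = 1
  expect_lt(abs(sd(b0) - 10), 0.3)          # N(0, 10^2) intercept
  expect_lt(abs(sd(b1) - 1), 0.05)          # N(0, 1) at unit HS scales
  expect_lt(abs(sd(r0) - 1), 0.05)          # N(0, 1) AR intercept
})

test_that("regression conditionals match a seeded conjugacy oracle", {
  fx <- samplerFixture(n = 25L, seed = 46L)
  hs <- list(lambda = list(beta1 = c(0.5, 1, 2), gamma1 = c(1, 0.7),
                           beta2 = c(2, 1, 0.5), gamma2 = c(0.7, 1)),
             tau = list(beta1 = 0.8, gamma1 = 1.2, beta2 = 0.6,
                        gamma2 = 1.1))
  z1 <- fx$mrd$z1; z2 <- fx$mrd$z2
  set.seed(47)
  draw <- BayesMRD:::updateRegressionDraw(fx$params, hs, fx$X, fx$C,
                                          fx$mrd, z1, z2)
  # oracle: re-derive the two conditional draws from the conjugate algebra,
  # consuming the identical RNG stream
  set.seed(47)
  n <- nrow(fx$X)
  oracleDraw <- function(W, z, sigma2, priorPrec) {
    A <- crossprod(W) / sigma2 + diag(priorPrec)
    R <- chol(A)
    m <- solve(A, crossprod(W, z) / sigma2)
    drop(m + backsolve(R, rnorm(ncol(W))))
  }
  W1 <- cbind(1, fx$X, fx$C)
  pr1 <- c(1 / 100, 1 / (hs$lambda$beta1 * hs$tau$beta1)^2,
           1 / (hs$lambda$gamma1 * hs$tau$gamma1)^2)
  b1 <- oracleDraw(W1, z1, fx$params$sigma2[1L], pr1)
  s1 <- 1 / rgamma(1L, shape = 3 + n / 2,
                   rate = 2 + sum((z1 - W1 %*% b1)^2) / 2)
  d1 <- fx$mrd$delta1
  W2 <- cbind(1, d1, d1 * fx$mrd$z1, d1 * fx$X, d1 * fx$C)
  pr2 <- c(1 / 100, 1, 1, 1 / (hs$lambda$beta2 * hs$tau$beta2)^2,
           1 / (hs$lambda$gamma2 * hs$tau$gamma2)^2)
  b2 <- oracleDraw(W2, z2, fx$params$sigma2[2L], pr2)
  s2 <- 1 / rgamma(1L, shape = 3 + n / 2,
                   rate = 2 + sum((z2 - W2 %*% b2)^2) / 2)
  expect_equal(unname(c(draw$beta0[1L], draw$beta1, draw$gamma1)),
               unname(b1), tolerance = 1e-9)
  expect_equal(draw$sigma2[1L], s1, tolerance = 1e-9)
  expect_equal(unname(c(draw$beta0[2L], draw$rho0, draw$rho, draw$beta2,
                        draw$gamma2)),
               unname(b2), tolerance = 1e-9)
  expect_equal(draw$sigma2[2L], s2, tolerance = 1e-9)
})

test_that("mixture conditionals have the right moments", {
  set.seed(48)
  Y <- matrix(rnorm(50), 10L, 5L)
  mix0 <- list(w = rep(1 / 3, 3L), mu = matrix(0, 3L, 5L),
               sigma2 = c(1, 1, 1))
  # Dirichlet mean with counts (10, 0, 0) and alpha = 1/3
  wAcc <- matrix(0, 4000L, 3L)
  for (r in seq_len(4000L))
    wAcc[r, ] <- BayesMRD:::updateMixtureDraw(mix0, rep(1L, 10L), Y)$w
  expect_equal(colMeans(wAcc), c(10 + 1 / 3, 1 / 3, 1 / 3) / 11,
               tolerance = 0.01)

  # single-member component: conditional mean (Y_i / sigma^2)/(1/sigma^2 + 1)
  alloc <- c(2L, rep(1L, 9L))
  mix1 <- list(w = rep(1 / 3, 3L), mu = matrix(0, 3L, 5L),
               sigma2 = c(1, 0.5, 1))
  muAcc <- matrix(0, 4000L, 5L)
  for (r in seq_len(4000L))
    muAcc[r, ] <- BayesMRD:::updateMixtureDraw(mix1, alloc, Y)$mu[2L, ]
  expect_equal(colMeans(muAcc), (Y[1L, ] / 0.5) / (1 / 0.5 + 1),
               tolerance = 0.05)

  # empty components are refreshed from the prior
  muE <- s2E <- numeric(0)
  for (r in seq_len(4000L)) {
    d <- BayesMRD:::updateMixtureDraw(mix0, rep(1L, 10L), Y)
    muE <- c(muE, d$mu[3L, 1L]); s2E <- c(s2E, d$sigma2[3L])
  }
  expect_lt(abs(mean(muE)), 0.05)
  expect_lt(abs(sd(muE) - 1), 0.05)
  expect_lt(abs(mean(s2E) - 1), 0.06)
})

test_that("the chain is deterministic and keeps the right number of draws", {
  cfg <- smallConfig(n = 50L, seed = 15L, missingRates = rep(0, 5))
  co <- simulateCohort(cfg)
  mc <- mcmcConfig(nIter = 300L, burnIn = 100L, thin = 2L, seed = 2L)
  f1 <- fitMRDModel(co, config = mc)
  f2 <- fitMRDModel(co, config = mc)
  expect_identical(nDraws(f1), 100L)
  expect_identical(f1@draws, f2@draws)
  expect_identical(f1@allocations, f2@allocations)
  # default configuration retains (15000 - 5000) / 2 draws
  dflt <- mcmcConfig()
  expect_identical((dflt$nIter - dflt$burnIn) %/% dflt$thin, 5000L)
  # imputed censored values always sit below the bound
  expect_true(all(posteriorDraws(f1, "imputedZ1") <= zLow(co)))
  expect_true(all(posteriorDraws(f1, "imputedZ2") <= zLow(co)))
  expect_error(mcmcConfig(nIter = 100L, burnIn = 200L), "burnIn")
})

test_that("the sampler recovers a unit autoregressive coefficient", {
  cfg <- cohortSimConfig(nPatients = 400L, seed = 16L,
                         missingRates = rep(0, 5))
  co <- simulateCohort(cfg)
  fit <- fitMRDModel(co, config = mcmcConfig(nIter = 3000L, burnIn = 1000L,
                                             thin = 2L, seed = 3L))
  rho <- posteriorDraws(fit, "coefficients2")[, "rho"]
  expect_lt(abs(median(rho) - 1.0), 0.15)
})

test_that("prior marginals are invariant under the joint update cycle", {
  # Geweke-style joint-distribution check on rho, sigma2^(1), w, run as
  # many short independent successive-conditional chains (fresh prior start
  # each restart, final draw kept): across restarts the kept draws are
  # exactly iid from the prior when every update is correct. Horseshoe
  # scales are pinned at 1 so the regression prior is N(0,1) on both sides.
  set.seed(49)
  n <- 20L
  X <- matrix(rnorm(n * 2L), n, 2L,
              dimnames = list(NULL, c("x1", "x2")))
  hs <- list(lambda = list(beta1 = rep(1, 2L), gamma1 = rep(1, 2L),
                           beta2 = rep(1, 2L), gamma2 = rep(1, 2L)),
             tau = list(beta1 = 1, gamma1 = 1, beta2 = 1, gamma2 = 1))
  gew <- gewekeRestarts(X, hs, nRestarts = 200L, length = 50L)
  expect_lt(abs(mean(gew$rho)), 0.25)
  expect_lt(abs(sd(gew$rho) - 1), 0.25)
  expect_gt(suppressWarnings(stats::ks.test(gew$rho, pnorm))$p.value,
            0.005)
  igCDF <- function(x) 1 - pgamma(1 / x, 3, rate = 2)
  expect_gt(suppressWarnings(stats::ks.test(gew$sigma2, igCDF))$p.value,
            0.005)
  expect_gt(suppressWarnings(stats::ks.test(gew$w1, pbeta,
                                            1 / 3, 2 / 3))$p.value,
            0.005)
})
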