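# Exact log-density computations for the joint model: the left-censored
# two-timepoint MRD likelihood, the Gaussian-mixture likelihood over LC50
# profiles, and all prior terms including the horseshoe hierarchy.

#' Conditional mean of log10 MRD at a time point
#'
#' Day-15 mean is a linear predictor in the covariates and the latent cluster
#' dummies. The day-42 mean gates the whole autoregressive block (AR intercept
#' `rho0`, AR slope `rho` times the day-15 value, covariate and cluster
#' effects) on day-15 detectability: for a patient censored at day 15 the mean
#' is the bare intercept `beta0[2]`, independent of covariates and clusters.
#'
#' @param params regression parameter list (`beta0`, `beta1`, `beta2`,
#'   `gamma1`, `gamma2`, `rho0`, `rho`, `sigma2`).
#' @param X design matrix (patients x p), see [designMatrix()].
#' @param C cluster dummy matrix (patients x 2), cluster 1 reference.
#' @param z1 current day-15 log10 MRD values (observed for detected patients).
#' @param delta1 day-15 detection indicators (0/1).
#' @param t time point, 1 (day 15) or 2 (day 42).
#' @return numeric vector of conditional means.
#' @export
mrdMean <- function(params, X, C, z1 = NULL, delta1 = NULL, t) {
  if (!t %in% c(1, 2)) stop("t must be 1 or 2")
  if (t == 1) {
    params$beta0[1L] + drop(X %*% params$beta1) + drop(C %*% params$gamma1)
  } else {
    params$beta0[2L] + delta1 *
      (params$rho0 + params$rho * z1 +
         drop(X %*% params$beta2) + drop(C %*% params$gamma2))
  }
}

#' Left-censored log-likelihood of the two-timepoint MRD observations
#'
#' Detected observations contribute a normal density term; censored
#' observations contribute the normal probability mass below the detection
#' threshold, `log Phi((zLow - mu)/sigma)`. The two time points factorise
#' given the parameters, with the day-42 mean gated on day-15 detectability.
#'
#' @param params regression parameter list; `sigma2` entries must be positive.
#' @param X,C design and cluster-dummy matrices.
#' @param mrd data.frame with `z1`, `delta1`, `z2`, `delta2` (censored entries
#'   store the bound).
#' @param zlow detection threshold on the log10-percent scale.
#' @return total log-likelihood (finite for finite parameters).
#' @export
mrdLogLik <- function(params, X, C, mrd, zlow = log10(0.01)) {
  if (any(params$sigma2 <= 0))
    stop("domain error: observation variances must be positive")
  s1 <- sqrt(params$sigma2[1L]); s2 <- sqrt(params$sigma2[2L])
  mu1 <- mrdMean(params, X, C, t = 1)
  mu2 <- mrdMean(params, X, C, z1 = mrd$z1, delta1 = mrd$delta1, t = 2)
  ll1 <- ifelse(mrd$delta1 == 1,
                dnorm(mrd$z1, mu1, s1, log = TRUE),
                pnorm(zlow, mu1, s1, log.p = TRUE))
  ll2 <- ifelse(mrd$delta2 == 1,
                dnorm(mrd$z2, mu2, s2, log = TRUE),
                pnorm(zlow, mu2, s2, log.p = TRUE))
  sum(ll1) + sum(ll2)
}

#' Gaussian-mixture log-likelihood of complete LC50 profiles
#'
#' In allocated form, each patient contributes `log w_c + log N(Y_i; mu_c,
#' sigma2_c I)` for their latent component `c`; a zero-weight component that
#' is occupied yields `-Inf`. The collapsed form marginalises the allocation
#' by log-sum-exp over components.
#'
#' @param mix mixture parameter list (`w`, `mu` 3 x d, `sigma2` length 3).
#' @param alloc integer allocations in `{1, 2, 3}` (ignored when
#'   `collapsed = TRUE`).
#' @param Y complete patients x d matrix (post-imputation, standardised
#'   scale).
#' @param collapsed marginalise allocations instead of conditioning on them.
#' @return total log-likelihood.
#' @export
mixtureLogLik <- function(mix, alloc, Y, collapsed = FALSE) {
  Y <- as.matrix(Y)
  d <- ncol(Y)
  compDens <- vapply(seq_along(mix$w), function(j) {
    s <- sqrt(mix$sigma2[j])
    rowSums(dnorm(Y, rep(mix$mu[j, ], each = nrow(Y)), s, log = TRUE))
  }, numeric(nrow(Y)))
  compDens <- matrix(compDens, nrow = nrow(Y))
  logw <- ifelse(mix$w > 0, log(mix$w), -Inf)
  if (collapsed) {
    sum(apply(sweep(compDens, 2L, logw, "+"), 1L, logsumexp))
  } else {
    sum(logw[alloc] + compDens[cbind(seq_len(nrow(Y)), alloc)])
  }
}

#' Joint log-prior of all model parameters
#'
#' Horseshoe hierarchy per coefficient block (`beta1`, `gamma1`, `beta2`,
#' `gamma2`): `beta_j | lambda_j, tau ~ N(0, lambda_j^2 tau^2)` with standard
#' half-Cauchy(0,1) local and global scales. Standard-normal priors on the AR
#' parameters `rho0`, `rho`; Inv-Gamma(3, 2) on all variances; N(0, 10^2) on
#' the two intercepts; Dirichlet(1/3, 1/3, 1/3) on the mixture weights and
#' N(0, I) on the component means.
#'
#' @param params regression parameter list.
#' @param hs horseshoe state: `lambda` (list of positive vectors per block)
#'   and `tau` (positive scalar per block).
#' @param mix mixture parameter list.
#' @return total log-prior density.
#' @export
logPriorDensity <- function(params, hs, mix) {
  blocks <- list(beta1 = params$beta1, gamma1 = params$gamma1,
                 beta2 = params$beta2, gamma2 = params$gamma2)
  lp <- 0
  for (b in names(blocks)) {
    lam <- hs$lambda[[b]]; tau <- hs$tau[[b]]
    if (any(lam <= 0) || tau <= 0)
      stop("domain error: horseshoe scales must be positive")
    lp <- lp + sum(dnorm(blocks[[b]], 0, lam * tau, log = TRUE)) +
      sum(dhalfcauchy_log(lam)) + dhalfcauchy_log(tau)
  }
  lp <- lp + sum(dnorm(params$beta0, 0, 10, log = TRUE)) +
    dnorm(params$rho0, 0, 1, log = TRUE) +
    dnorm(params$rho, 0, 1, log = TRUE) +
    sum(dinvgamma_log(params$sigma2, 3, 2)) +
    ddirichlet_log(mix$w, rep(1 / 3, length(mix$w))) +
    sum(dnorm(mix$mu, 0, 1, log = TRUE)) +
    sum(dinvgamma_log(mix$sigma2, 3, 2))
  lp
}

#' Joint log-density: likelihoods plus prior
#'
#' Sum of [mrdLogLik()], [mixtureLogLik()] (allocated form) and
#' [logPriorDensity()]; used by the sampler's sanity checks and by tests.
#'
#' @param state list with `params`, `hs`, `mix`, `alloc`.
#' @param X,C,mrd,Y,zlow data blocks as in the component functions.
#' @return total log-density.
#' @export
logJointDensity <- function(state, X, C, mrd, Y, zlow = log10(0.01)) {
  mrdLogLik(state$params, X, C, mrd, zlow) +
    mixtureLogLik(state$mix, state$alloc, Y) +
    logPriorDensity(state$params, state$hs, state$mix)
}
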