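# Convergence diagnostics: split-Rhat and effective sample size computed on
# the retained draws (rank-free, classical formulation).

## Arrange draws into split half-chains: an n x m matrix of chains becomes an
## (n/2) x 2m matrix.
splitChains <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- n %/% 2L
  x <- x[seq_len(2L * half), , drop = FALSE]
  do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
    cbind(x[seq_len(half), j], x[half + seq_len(half), j])
  }))
}

#' Split-Rhat potential scale reduction
#'
#' Each supplied chain is split in half and the classical potential scale
#' reduction factor is computed across the resulting half-chains:
#' `sqrt(((n-1)/n W + B/n) / W)` with `W` the mean within-chain variance and
#' `B` the between-chain variance of the means. Returns `NA` for degenerate
#' (constant) chains.
#'
#' @param x numeric vector (single chain) or matrix with one chain per
#'   column.
#' @return scalar Rhat estimate.
#' @export
splitRhat <- function(x) {
  ch <- splitChains(x)
  n <- nrow(ch)
  if (n < 2L) stop("need at least 4 draws for split-Rhat")
  W <- mean(apply(ch, 2L, stats::var))
  B <- n * stats::var(colMeans(ch))
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size of MCMC draws
#'
#' Multi-chain effective sample size from the combined autocorrelation
#' estimate (within-chain autocovariances pooled against the overall variance
#' estimate), truncated by Geyer's initial positive-pair-sum rule. Chains are
#' split in half first, as for [splitRhat()]. Constant chains return `NA`.
#'
#' @param x numeric vector (single chain) or matrix with one chain per
#'   column.
#' @return scalar effective sample size.
#' @export
effectiveSampleSize <- function(x) {
  ch <- splitChains(x)
  n <- nrow(ch); m <- ncol(ch)
  if (n < 2L) stop("need at least 4 draws for effective sample size")
  W <- mean(apply(ch, 2L, stats::var))
  B <- n * stats::var(colMeans(ch))
  varPlus <- (n - 1) / n * W + B / n
  if (!is.finite(varPlus) || varPlus == 0) return(NA_real_)
  acov <- vapply(seq_len(m), function(j) {
    a <- stats::acf(ch[, j], lag.max = n - 1L, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1L, 1L]
    a
  }, numeric(n))
  rho <- 1 - (W - rowMeans(acov)) / varPlus   # rho[1] corresponds to lag 0
  tau <- 1
  t <- 2L
  while (t + 1L <= n) {
    pairSum <- rho[t] + rho[t + 1L]
    if (!is.finite(pairSum) || pairSum < 0) break
    tau <- tau + 2 * pairSum
    t <- t + 2L
  }
  max(n * m / tau, 1)
}

#' Convergence diagnostics table for a fitted model
#'
#' Split-Rhat and effective sample size for every scalar parameter in the
#' regression, variance and mixture blocks, with a warning listing parameters
#' whose Rhat exceeds 1.05.
#'
#' @param fit an [MRDFit-class] (needs at least 4 retained draws).
#' @param blocks draw blocks to include.
#' @return data.frame with columns `parameter`, `mean`, `rhat`, `ess`.
#' @export
mcmcDiagnostics <- function(fit,
                            blocks = c("coefficients1", "coefficients2",
                                       "sigma2", "mixtureWeights",
                                       "mixtureVars")) {
  if (nDraws(fit) < 4L) stop("need at least 4 retained draws for diagnostics")
  rows <- lapply(blocks, function(b) {
    mat <- posteriorDraws(fit, b)
    data.frame(parameter = paste0(b, ".", colnames(mat)),
               mean = colMeans(mat),
               rhat = apply(mat, 2L, splitRhat),
               ess = apply(mat, 2L, effectiveSampleSize),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  bad <- out$parameter[!is.na(out$rhat) & out$rhat > 1.05]
  if (length(bad))
    warning("Rhat > 1.05 for: ", paste(bad, collapse = ", "))
  out
}
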