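# Internal numeric helpers shared across modules.

#' @importFrom stats rgamma dnorm pnorm qnorm runif rnorm rbinom sd
#'   quantile median kmeans lm rchisq complete.cases setNames
NULL

## Dirichlet draw via normalised gammas; alpha > 0.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) { # numerically possible for tiny alpha
    g[sample.int(length(alpha), 1L)] <- 1
  }
  g / sum(g)
}

## Inverse-gamma draws / log-density, shape a, rate (scale of 1/x) b:
## mean b/(a-1) for a > 1.
rinvgamma <- function(n, shape, rate) 1 / rgamma(n, shape = shape, rate = rate)

dinvgamma_log <- function(x, shape, rate) {
  ifelse(x > 0,
         shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x,
         -Inf)
}

## Half-Cauchy(0, 1) log-density on (0, Inf).
dhalfcauchy_log <- function(x) {
  ifelse(x > 0, log(2) - log(pi) - log1p(x^2), -Inf)
}

ddirichlet_log <- function(w, alpha) {
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) return(-Inf)
  if (any(w == 0 & alpha != 1)) return(if (any(w == 0 & alpha > 1)) -Inf else Inf)
  lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * log(w))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## k-means++ seeding: first centre uniform, later centres with probability
## proportional to squared distance from the nearest chosen centre.
kmeansppCenters <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  if (k > 1L) {
    d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2L:k) {
      prob <- d2 / sum(d2)
      if (!all(is.finite(prob)) || sum(d2) == 0) prob <- rep(1 / n, n)
      idx <- sample.int(n, 1L, prob = prob)
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
    }
  }
  centers
}

## Multi-restart k-means with k-means++ seeding; returns the stats::kmeans fit
## with the lowest total within-cluster sum of squares.
kmeansRestart <- function(x, k, nRestarts = 10L, iterMax = 100L) {
  x <- as.matrix(x)
  if (k >= nrow(x)) {
    if (k > nrow(x)) stop("k must be smaller than the number of observations")
    # one point per cluster: WSS is exactly 0
    fit <- list(cluster = seq_len(nrow(x)), centers = x,
                tot.withinss = 0, withinss = rep(0, k))
    return(fit)
  }
  best <- NULL
  for (r in seq_len(nRestarts)) {
    init <- kmeansppCenters(x, k)
    fit <- tryCatch(
      kmeans(x, centers = init, iter.max = iterMax),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch(kmeans(x, centers = k, iter.max = iterMax, nstart = 1L),
                      error = function(e) NULL)
    }
    if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss))
      best <- fit
  }
  if (is.null(best)) stop("k-means failed for k = ", k)
  best
}

## Column-wise z-score standardisation; returns matrix with centre/scale
## attributes so reported summaries can be mapped back to the raw scale.
standardizeColumns <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, sd)
  scl[scl == 0] <- 1
  out <- sweep(sweep(x, 2L, ctr, "-"), 2L, scl, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}
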