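#' Multiple imputation of missing LC50 values by chained equations
#'
#' Produces `m` completed copies of the patients x drugs log10 LC50 matrix.
#' Missing entries are initialised by resampling observed values in the same
#' column, then refined over a fixed number of sweeps: each sweep cycles over
#' the columns, fits a Bayesian normal linear regression of the column on all
#' other (current-state) columns using the rows where the column is observed,
#' draws the residual variance and coefficients from their posterior, and
#' replaces the column's missing entries with posterior-predictive draws.
#' Observed entries are never modified. A small ridge term and weakly
#' informative inverse-gamma variance prior keep the conditionals proper even
#' on small or collinear fixtures.
#'
#' @param x an [MRDCohort-class] (its `lc50` assay is used) or a numeric
#'   matrix with `NA` for missing entries.
#' @param m number of imputations (default 100).
#' @param sweeps chained-equation sweeps per imputation (default 10).
#' @param seed integer seed.
#' @return an [LC50Imputations-class] object.
#' @export
imputeLC50 <- function(x, m = 100L, sweeps = 10L, seed = 1L) {
  Y <- if (is(x, "MRDCohort")) lc50Matrix(x) else as.matrix(x)
  if (is.null(colnames(Y)))
    colnames(Y) <- paste0("drug", seq_len(ncol(Y)))
  if (nrow(Y) < 2L) stop("data error: need at least two patients")
  mask <- is.na(Y)
  fullRow <- which(rowSums(!mask) == 0L)
  if (length(fullRow))
    stop("data error: row(s) entirely missing: ",
         paste(fullRow, collapse = ", "))
  obsPerCol <- colSums(!mask)
  if (any(obsPerCol < 2L))
    stop("data error: column(s) with fewer than 2 observed entries: ",
         paste(colnames(Y)[obsPerCol < 2L], collapse = ", "))
  set.seed(seed)
  d <- ncol(Y)
  completed <- vector("list", m)
  for (im in seq_len(m)) {
    cur <- Y
    for (j in seq_len(d)) {           # initial fill: sample observed values
      mj <- mask[, j]
      if (any(mj))
        cur[mj, j] <- sample(Y[!mj, j], sum(mj), replace = TRUE)
    }
    for (s in seq_len(sweeps)) {
      for (j in seq_len(d)) {
        mj <- mask[, j]
        if (!any(mj)) next
        cur[mj, j] <- drawColumnImputation(cur, Y[, j], mj, j)
      }
    }
    completed[[im]] <- cur
  }
  new("LC50Imputations", completed = completed, mask = mask,
      drugNames = colnames(Y), method = "bayes-norm-chained",
      seed = as.integer(seed), sweeps = as.integer(sweeps))
}

## One Bayesian-regression imputation step for column j: posterior draw of
## (sigma2, beta) given the observed rows, then predictive draws for the
## missing rows. Ridge 1e-5 on the normal equations; IG(0.01, 0.01) on the
## residual variance.
drawColumnImputation <- function(cur, yObsCol, missIdx, j) {
  X <- cbind(1, cur[, -j, drop = FALSE])
  Xobs <- X[!missIdx, , drop = FALSE]
  yobs <- yObsCol[!missIdx]
  p <- ncol(Xobs)
  XtX <- crossprod(Xobs) + diag(1e-5, p)
  Xty <- crossprod(Xobs, yobs)
  R <- chol(XtX)
  betaHat <- backsolve(R, forwardsolve(t(R), Xty))
  rss <- sum((yobs - drop(Xobs %*% betaHat))^2)
  sigma2 <- rinvgamma(1L, shape = 0.01 + length(yobs) / 2,
                      rate = 0.01 + rss / 2)
  beta <- betaHat + sqrt(sigma2) * backsolve(R, rnorm(p))
  Xmis <- X[missIdx, , drop = FALSE]
  drop(Xmis %*% beta) + rnorm(sum(missIdx), 0, sqrt(sigma2))
}

#' Within-cluster sum-of-squares elbow curves across imputations
#'
#' Runs multi-restart k-means (k-means++ seeding, best total WSS kept) on
#' each completed matrix for each candidate number of clusters, and averages
#' the curves across imputations. Columns are z-scored per drug before
#' clustering by default, matching the standardised scale on which the
#' mixture model operates.
#'
#' @param imps an [LC50Imputations-class].
#' @param kValues candidate cluster counts (default 1:10).
#' @param nRestarts k-means restarts per (imputation, k) (default 10).
#' @param seed integer seed.
#' @param standardize z-score columns before clustering (default `TRUE`).
#' @return a [WSSCurve-class].
#' @export
wssCurve <- function(imps, kValues = 1:10, nRestarts = 10L, seed = 1L,
                     standardize = TRUE) {
  kValues <- sort(unique(as.integer(kValues)))
  n <- nrow(imps@completed[[1L]])
  if (any(kValues < 1L) || any(kValues > n))
    stop("parameter error: kValues must lie in 1..N")
  set.seed(seed)
  m <- length(imps@completed)
  W <- matrix(NA_real_, m, length(kValues),
              dimnames = list(NULL, paste0("k", kValues)))
  for (im in seq_len(m)) {
    Y <- imps@completed[[im]]
    if (standardize) Y <- standardizeColumns(Y)
    for (ik in seq_along(kValues)) {
      W[im, ik] <- kmeansRestart(Y, kValues[ik], nRestarts)$tot.withinss
    }
  }
  new("WSSCurve", kValues = kValues, perImputation = W,
      meanWSS = colMeans(W), standardized = standardize)
}

#' Select the imputed data set used for the main analysis
#'
#' Returns the (1-based) index of the completed matrix with the lowest total
#' within-cluster sum of squares at the chosen number of clusters; ties are
#' broken by the lowest index.
#'
#' @param imps an [LC50Imputations-class].
#' @param wss a [WSSCurve-class] computed from `imps`.
#' @param k number of clusters at which to compare (default 3).
#' @return integer index into `imps@completed`.
#' @export
selectImputation <- function(imps, wss, k = 3L) {
  ik <- match(as.integer(k), wss@kValues)
  if (is.na(ik)) stop("parameter error: k not among the curve's kValues")
  which.min(wss@perImputation[, ik])
}

#' @describeIn imputeLC50 compact display of an imputation set.
#' @param object an `LC50Imputations`.
#' @export
setMethod("show", "LC50Imputations", function(object) {
  dims <- dim(object@completed[[1L]])
  cat("LC50Imputations:", length(object@completed), "completions of a",
      dims[1L], "x", dims[2L], "matrix\n")
  cat(sprintf("  missing entries: %.1f%%; method %s; %d sweeps; seed %d\n",
              100 * mean(object@mask), object@method, object@sweeps,
              object@seed))
})

#' @describeIn wssCurve compact display of the mean elbow curve.
#' @param object a `WSSCurve`.
#' @export
setMethod("show", "WSSCurve", function(object) {
  cat("WSSCurve over", nrow(object@perImputation), "imputations\n")
  print(data.frame(k = object@kValues, meanWSS = object@meanWSS),
        row.names = FALSE)
})
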