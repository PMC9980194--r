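# Posterior summaries: coefficient tables with credible-interval selection,
# the posterior similarity matrix, Binder-loss partition point estimates,
# per-cluster profiles, and posterior means of the censored MRD values.

#' Posterior similarity matrix
#'
#' N x N matrix of pairwise co-clustering frequencies across the retained
#' allocation draws: entry (i, j) is the fraction of draws in which patients
#' i and j share a mixture component. Symmetric with unit diagonal; invariant
#' to label switching.
#'
#' @param x an [MRDFit-class] or an integer draws x patients allocation
#'   matrix.
#' @return numeric N x N matrix.
#' @export
setGeneric("similarityMatrix", function(x) standardGeneric("similarityMatrix"))

#' @rdname similarityMatrix
#' @export
setMethod("similarityMatrix", "MRDFit", function(x) {
  similarityMatrix(x@allocations)
})

#' @rdname similarityMatrix
#' @export
setMethod("similarityMatrix", "matrix", function(x) {
  D <- nrow(x)
  n <- ncol(x)
  psm <- matrix(0, n, n)
  for (j in sort(unique(as.vector(x)))) {
    M <- (x == j) * 1
    psm <- psm + crossprod(M)
  }
  psm <- psm / D
  diag(psm) <- 1
  if (!is.null(colnames(x)))
    dimnames(psm) <- list(colnames(x), colnames(x))
  psm
})

#' Binder loss of a partition against a similarity matrix
#'
#' Equal-cost Binder loss: `sum_{i<j} | 1[c_i = c_j] - psm_ij |`, counting
#' pairwise disagreements between a hard partition and the posterior
#' co-clustering probabilities.
#'
#' @param labels integer cluster labels, one per patient.
#' @param psm posterior similarity matrix from [similarityMatrix()].
#' @return non-negative scalar loss.
#' @export
binderLoss <- function(labels, psm) {
  n <- length(labels)
  if (!identical(dim(psm), c(n, n)))
    stop("dimension mismatch between labels and similarity matrix")
  eq <- outer(labels, labels, "==") * 1
  sum(abs(eq - psm)[upper.tri(psm)])
}

## Binder loss up to a candidate-independent constant:
## loss = sum_{i<j} psm + sum_{i<j} eq_ij (1 - 2 psm_ij); Q = 1 - 2 psm.
binderQuadForm <- function(labels, Q) {
  tot <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    tot <- tot + sum(Q[idx, idx]) - sum(diag(Q)[idx])
  }
  tot / 2
}

#' Binder-loss partition point estimate
#'
#' Scans candidate partitions (by default the sampled allocation draws,
#' subsampled evenly when there are many) for the lowest Binder loss against
#' the posterior similarity matrix, then refines the best candidate by greedy
#' single-patient reassignment sweeps until no move lowers the loss. By
#' construction the result's loss never exceeds that of any scanned draw.
#'
#' @param x an [MRDFit-class], or a posterior similarity matrix when
#'   `candidates` is supplied.
#' @param candidates optional matrix of candidate partitions (one row each).
#' @param maxCandidates cap on scanned candidate draws (evenly thinned).
#' @param maxSweeps cap on greedy refinement sweeps.
#' @return list of class `BinderPartition` with `labels` (contiguous from 1,
#'   in order of first appearance), `nClusters`, `sizes`, `loss`, and the
#'   `psm` used.
#' @export
binderPartition <- function(x, candidates = NULL, maxCandidates = 200L,
                            maxSweeps = 20L) {
  if (is(x, "MRDFit")) {
    psm <- similarityMatrix(x)
    if (is.null(candidates)) candidates <- x@allocations
  } else {
    psm <- x
    if (is.null(candidates))
      stop("candidates are required when a similarity matrix is given")
  }
  candidates <- as.matrix(candidates)
  if (nrow(candidates) > maxCandidates) {
    pick <- unique(round(seq(1L, nrow(candidates),
                             length.out = maxCandidates)))
    candidates <- candidates[pick, , drop = FALSE]
  }
  Q <- 1 - 2 * psm
  qf <- apply(candidates, 1L, binderQuadForm, Q = Q)
  best <- candidates[which.min(qf), ]

  ## Greedy sweeps: move one patient at a time to the cluster minimising its
  ## summed (1 - 2 psm) affinity, always keeping one empty cluster on offer
  ## so the sweep can also split clusters; ties keep the current assignment.
  n <- length(best)
  for (s in seq_len(maxSweeps)) {
    changed <- FALSE
    best <- match(best, sort(unique(best)))   # contiguous labels
    K <- max(best) + 1L                       # last label is an empty spare
    M <- vapply(seq_len(K), function(g) (best == g) * 1, numeric(n))
    S <- Q %*% M                       # n x K affinity sums (self included)
    for (i in seq_len(n)) {
      cur <- best[i]
      contrib <- S[i, ] - (seq_len(K) == cur) * Q[i, i]
      newk <- which.min(contrib)
      if (contrib[newk] < contrib[cur] - 1e-12) {
        S[, cur] <- S[, cur] - Q[, i]
        S[, newk] <- S[, newk] + Q[, i]
        best[i] <- newk
        changed <- TRUE
        if (newk == K) {               # spare used: open a fresh one
          K <- K + 1L
          S <- cbind(S, 0)
        }
      }
    }
    if (!changed) break
  }
  ## relabel contiguously in order of first appearance
  labels <- match(best, unique(best))
  out <- list(labels = labels,
              nClusters = length(unique(labels)),
              sizes = tabulate(labels),
              loss = binderLoss(labels, psm),
              psm = psm)
  class(out) <- "BinderPartition"
  out
}

#' @export
print.BinderPartition <- function(x, ...) {
  cat("Binder-loss partition:", x$nClusters, "clusters of sizes",
      paste(x$sizes, collapse = "/"),
      sprintf("(loss %.2f)\n", x$loss))
  invisible(x)
}

## Posterior summary of a draw matrix: mean, median, equal-tailed 95%
## interval (type-7 quantiles), and the credible-interval selection flag.
summarizeDrawMatrix <- function(mat) {
  q <- apply(mat, 2L, quantile, probs = c(0.025, 0.975), type = 7)
  data.frame(parameter = colnames(mat),
             mean = colMeans(mat),
             median = apply(mat, 2L, median),
             lower95 = q[1L, ], upper95 = q[2L, ],
             selected = q[1L, ] > 0 | q[2L, ] < 0,
             row.names = NULL)
}

#' Coefficient summary table with credible-interval selection
#'
#' Per coefficient: posterior mean, median, equal-tailed 95% credible
#' interval (empirical type-7 quantiles) and a `selected` flag marking
#' coefficients whose interval excludes zero. Day-15 and day-42 blocks are
#' prefixed `day15.` / `day42.`; the observation variances are appended. The
#' autoregressive coefficient's median and interquartile range are attached
#' as attribute `"rho"`.
#'
#' @param fit an [MRDFit-class]; intended for at least 100 retained draws.
#' @return data.frame of coefficient summaries.
#' @export
summarizeCoefficients <- function(fit) {
  if (nDraws(fit) < 100L)
    warning("fewer than 100 retained draws; interval estimates are crude")
  c1 <- posteriorDraws(fit, "coefficients1")
  c2 <- posteriorDraws(fit, "coefficients2")
  s2 <- posteriorDraws(fit, "sigma2")
  colnames(c1) <- paste0("day15.", colnames(c1))
  colnames(c2) <- paste0("day42.", colnames(c2))
  out <- summarizeDrawMatrix(cbind(c1, c2, s2))
  rho <- posteriorDraws(fit, "coefficients2")[, "rho"]
  attr(out, "rho") <- list(median = median(rho),
                           iqr = unname(quantile(rho, c(0.25, 0.75),
                                                 type = 7)))
  out
}

#' Per-cluster profiles of drug sensitivity and subtype composition
#'
#' For each cluster of a partition: mean and quartiles of each drug's log10
#' LC50, and the proportion of patients in each subtype category (rows sum to
#' one). These are the tabular analogues of per-cluster radar displays.
#'
#' @param partition a `BinderPartition` or integer label vector.
#' @param Y complete patients x drugs LC50 matrix (raw scale for reporting).
#' @param subtypes factor/character of subtype labels per patient.
#' @return list with data.frames `lc50` (cluster, drug, mean, q25, median,
#'   q75) and `subtypes` (cluster x subtype proportions).
#' @export
clusterProfiles <- function(partition, Y, subtypes) {
  labels <- if (inherits(partition, "BinderPartition")) partition$labels
            else as.integer(partition)
  Y <- as.matrix(Y)
  if (length(labels) != nrow(Y) || length(subtypes) != nrow(Y))
    stop("partition must cover all patients")
  subtypes <- factor(subtypes)
  ks <- seq_len(max(labels))
  lc50 <- do.call(rbind, lapply(ks, function(g) {
    idx <- which(labels == g)
    if (!length(idx)) {
      warning("cluster ", g, " is empty")
      return(data.frame(cluster = g, drug = colnames(Y), mean = NA_real_,
                        q25 = NA_real_, median = NA_real_, q75 = NA_real_))
    }
    Yg <- Y[idx, , drop = FALSE]
    qs <- apply(Yg, 2L, quantile, probs = c(0.25, 0.5, 0.75), type = 7)
    data.frame(cluster = g, drug = colnames(Y), mean = colMeans(Yg),
               q25 = qs[1L, ], median = qs[2L, ], q75 = qs[3L, ],
               row.names = NULL)
  }))
  props <- t(vapply(ks, function(g) {
    idx <- which(labels == g)
    if (!length(idx)) return(rep(NA_real_, nlevels(subtypes)))
    as.vector(table(subtypes[idx]) / length(idx))
  }, numeric(nlevels(subtypes))))
  dimnames(props) <- list(paste0("cluster", ks), levels(subtypes))
  list(lc50 = lc50, subtypes = as.data.frame(props))
}

#' Posterior means of censored MRD values
#'
#' Per patient and time point: observed values are passed through unchanged;
#' censored entries are replaced by the posterior mean of their within-MCMC
#' truncated-normal imputations (always at or below the detection bound).
#'
#' @param fit an [MRDFit-class].
#' @param cohort the [MRDCohort-class] the model was fitted to.
#' @return data.frame with columns `patient`, `day`, `value`, `censored`.
#' @export
censoredPosteriorMeans <- function(fit, cohort) {
  mrd <- mrdValues(cohort)
  n <- nrow(mrd)
  v1 <- mrd$z1
  v1[fit@dataInfo$censoredDay15] <- colMeans(posteriorDraws(fit, "imputedZ1"))
  v2 <- mrd$z2
  v2[fit@dataInfo$censoredDay42] <- colMeans(posteriorDraws(fit, "imputedZ2"))
  data.frame(
    patient = rep(rownames(mrd), 2L),
    day = rep(c(15L, 42L), each = n),
    value = c(v1, v2),
    censored = c(mrd$delta1 == 0L, mrd$delta2 == 0L),
    row.names = NULL)
}
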