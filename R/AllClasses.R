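#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' Cohort container for the joint MRD / drug-sensitivity analysis
#'
#' `MRDCohort` extends [SummarizedExperiment::SummarizedExperiment] with
#' patients as columns. The single assay, `"lc50"`, holds the log10 LC50
#' drug-sensitivity matrix (drugs in rows, `NA` marking missing assays).
#' `colData` carries the baseline covariates (age in years, male indicator,
#' log10 WBC, ALL subtype, treatment protocol) together with the two MRD
#' measurements on the log10-percent scale: `z1`/`z2` store the observed
#' values, or the detection bound `zLow` when censored, and `delta1`/`delta2`
#' are the censoring indicators (1 = detected, 0 = below the 0.01% limit).
#'
#' @slot zLow log10-percent detection threshold (default `log10(0.01) = -2`).
#'
#' @seealso [MRDCohort()] for construction, [simulateCohort()],
#'   [readCohort()].
#' @export
setClass("MRDCohort",
  contains = "SummarizedExperiment",
  representation(zLow = "numeric"))

setValidity("MRDCohort", function(object) {
  cd <- colData(object)
  need <- c("age", "male", "log10WBC", "subtype", "protocol",
            "z1", "delta1", "z2", "delta2")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste("colData lacks column(s):", paste(miss, collapse = ", ")))
  if (length(object@zLow) != 1L || !is.finite(object@zLow))
    return("zLow must be a single finite number")
  for (t in 1:2) {
    z <- cd[[paste0("z", t)]]
    d <- cd[[paste0("delta", t)]]
    if (!all(d %in% c(0, 1))) return("censoring indicators must be 0/1")
    if (any(d == 1 & z <= object@zLow))
      return("detected MRD values must exceed zLow")
    if (any(d == 0 & z != object@zLow))
      return("censored MRD values must store the bound zLow")
  }
  if (any(cd$age <= 0)) return("age must be positive")
  if (!all(cd$male %in% c(0, 1))) return("male indicator must be 0/1")
  TRUE
})

#' Multiple imputations of a drug-sensitivity matrix
#'
#' Holds `m` completed copies of an N x d log10 LC50 matrix produced by
#' chained-equation imputation. Observed entries are identical across copies.
#'
#' @slot completed list of completed numeric matrices (patients in rows).
#' @slot mask logical matrix, `TRUE` where the original entry was missing.
#' @slot drugNames character vector of column labels.
#' @slot method imputation method tag.
#' @slot seed integer seed used.
#' @slot sweeps number of chained-equation sweeps per imputation.
#' @export
setClass("LC50Imputations",
  representation(completed = "list", mask = "matrix", drugNames = "character",
                 method = "character", seed = "integer", sweeps = "integer"))

setValidity("LC50Imputations", function(object) {
  if (length(object@completed) < 1L) return("need at least one completion")
  dims <- dim(object@completed[[1L]])
  for (mat in object@completed) {
    if (!identical(dim(mat), dims)) return("completions differ in shape")
    if (anyNA(mat)) return("completed matrices must be complete")
  }
  if (!identical(dim(object@mask), dims)) return("mask shape mismatch")
  TRUE
})

#' Within-cluster sum-of-squares elbow curves across imputations
#'
#' @slot kValues candidate numbers of clusters.
#' @slot perImputation m x |k| matrix of total WSS from k-means on each
#'   completed data set.
#' @slot meanWSS column means of `perImputation`.
#' @slot standardized whether columns were z-scored before clustering.
#' @export
setClass("WSSCurve",
  representation(kValues = "integer", perImputation = "matrix",
                 meanWSS = "numeric", standardized = "logical"))

setValidity("WSSCurve", function(object) {
  if (ncol(object@perImputation) != length(object@kValues))
    return("perImputation must have one column per k")
  if (length(object@meanWSS) != length(object@kValues))
    return("meanWSS length mismatch")
  if (max(abs(object@meanWSS - colMeans(object@perImputation))) > 1e-8)
    return("meanWSS must be the column mean of perImputation")
  TRUE
})

#' Posterior draws from the joint MRD / mixture model
#'
#' Thinned post-burn-in Gibbs draws. `draws` is a named list of numeric
#' matrices, one row per retained draw:
#' `coefficients1` (day-15 regression: intercept, covariates, cluster
#' dummies), `coefficients2` (day-42 regression: intercept, rho0, rho,
#' covariates, cluster dummies), `sigma2` (two observation variances),
#' `mixtureWeights`, `mixtureMeans` (component x drug, column-major),
#' `mixtureVars`, `hsTau` (global shrinkage scales per coefficient block),
#' `logJoint`, and the truncated-normal imputations `imputedZ1`/`imputedZ2`
#' for censored MRD entries. `allocations` is an integer matrix of latent
#' cluster memberships (draw x patient).
#'
#' @slot draws named list of draw matrices.
#' @slot allocations integer matrix of mixture memberships per draw.
#' @slot config MCMC configuration list (`nIter`, `burnIn`, `thin`, `seed`).
#' @slot dataInfo bookkeeping: patient count, censored index sets, drug and
#'   coefficient names, standardisation attributes of the fitted LC50 matrix.
#' @export
setClass("MRDFit",
  representation(draws = "list", allocations = "matrix",
                 config = "list", dataInfo = "list"))

setValidity("MRDFit", function(object) {
  n <- nrow(object@allocations)
  for (nm in names(object@draws)) {
    if (nrow(object@draws[[nm]]) != n)
      return(paste0("draw matrix '", nm, "' has inconsistent draw count"))
  }
  TRUE
})
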