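#' Construct an MRDCohort
#'
#' Assembles the cohort container from a covariate table, MRD observations and
#' an LC50 matrix. MRD values are supplied on the log10-percent scale (`z1`,
#' `z2`), with censored entries stored at the detection bound `zLow` and
#' flagged by `delta1`/`delta2` equal to 0.
#'
#' @param covariates data.frame with columns `age` (years), `male` (0/1),
#'   `log10WBC`, `subtype` (factor or character), `protocol` (factor or
#'   character), one row per patient.
#' @param mrd data.frame with columns `z1`, `delta1`, `z2`, `delta2`.
#' @param lc50 numeric matrix, patients in rows and drugs in columns; `NA`
#'   marks a missing assay.
#' @param zLow log10-percent detection threshold; default `log10(0.01)`.
#' @param patientID optional character ids; defaults to `P1..PN`.
#' @return An [MRDCohort-class] object.
#' @export
MRDCohort <- function(covariates, mrd, lc50, zLow = log10(0.01),
                      patientID = NULL) {
  n <- nrow(covariates)
  lc50 <- as.matrix(lc50)
  if (nrow(mrd) != n || nrow(lc50) != n)
    stop("covariates, mrd and lc50 must describe the same patients")
  if (is.null(patientID)) patientID <- paste0("P", seq_len(n))
  if (is.null(colnames(lc50)))
    colnames(lc50) <- paste0("drug", seq_len(ncol(lc50)))
  cd <- DataFrame(
    age = as.numeric(covariates$age),
    male = as.integer(covariates$male),
    log10WBC = as.numeric(covariates$log10WBC),
    subtype = if (is.factor(covariates$subtype)) covariates$subtype
              else factor(covariates$subtype),
    protocol = if (is.factor(covariates$protocol)) covariates$protocol
               else factor(covariates$protocol),
    z1 = as.numeric(mrd$z1), delta1 = as.integer(mrd$delta1),
    z2 = as.numeric(mrd$z2), delta2 = as.integer(mrd$delta2),
    row.names = patientID)
  se <- SummarizedExperiment(
    assays = list(lc50 = t(lc50)),
    colData = cd)
  new("MRDCohort", se, zLow = zLow)
}

#' @rdname MRDCohort
#' @param x,object an `MRDCohort`.
#' @export
setGeneric("lc50Matrix", function(x) standardGeneric("lc50Matrix"))

#' @describeIn MRDCohort patients x drugs log10 LC50 matrix (`NA` = missing).
#' @export
setMethod("lc50Matrix", "MRDCohort", function(x) t(assay(x, "lc50")))

#' @rdname MRDCohort
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @describeIn MRDCohort logical patients x drugs missingness mask.
#' @export
setMethod("missingMask", "MRDCohort", function(x) is.na(lc50Matrix(x)))

#' @rdname MRDCohort
#' @export
setGeneric("zLow", function(x) standardGeneric("zLow"))

#' @describeIn MRDCohort the log10-percent detection threshold.
#' @export
setMethod("zLow", "MRDCohort", function(x) x@zLow)

#' @rdname MRDCohort
#' @export
setGeneric("mrdValues", function(x) standardGeneric("mrdValues"))

#' @describeIn MRDCohort data.frame of `z1`, `delta1`, `z2`, `delta2`.
#' @export
setMethod("mrdValues", "MRDCohort", function(x) {
  cd <- colData(x)
  data.frame(z1 = cd$z1, delta1 = cd$delta1, z2 = cd$z2, delta2 = cd$delta2,
             row.names = rownames(cd))
})

#' Regression design matrix for the MRD model
#'
#' Builds the fixed covariate design used at both time points, one row per
#' patient, columns in a documented order: `age` (years), `Female` indicator
#' (Male is the reference level for reporting), `log10WBC`, then one dummy per
#' non-reference ALL subtype in lexical order (reference `ETV6-RUNX1` when
#' present, otherwise the first level), then one dummy per non-reference
#' protocol (reference `T16` when present). Cluster-membership dummies are not
#' part of this matrix; they are handled by the sampler because memberships
#' are latent.
#'
#' @param cohort an [MRDCohort-class].
#' @return numeric matrix with named columns.
#' @export
designMatrix <- function(cohort) {
  cd <- colData(cohort)
  X <- designMatrixFromDF(as.data.frame(cd))
  rownames(X) <- rownames(cd)
  X
}

## Dummy coding of mixture memberships: cluster 1 is the reference,
## c = (1,0) is cluster 2 and c = (0,1) is cluster 3.
allocationDummies <- function(alloc, k = 3L) {
  C <- matrix(0, length(alloc), k - 1L)
  for (j in 2L:k) C[alloc == j, j - 1L] <- 1
  colnames(C) <- paste0("Cluster", 2L:k)
  C
}

#' @describeIn MRDCohort compact display.
#' @export
setMethod("show", "MRDCohort", function(object) {
  cd <- colData(object)
  cat("MRDCohort with", ncol(object), "patients,",
      nrow(object), "drugs (assay 'lc50')\n")
  cat(sprintf("  censored MRD: day 15 %d/%d (%.1f%%), day 42 %d/%d (%.1f%%)\n",
              sum(cd$delta1 == 0), ncol(object),
              100 * mean(cd$delta1 == 0),
              sum(cd$delta2 == 0), ncol(object),
              100 * mean(cd$delta2 == 0)))
  cat(sprintf("  missing LC50 entries: %.1f%%; zLow = %g\n",
              100 * mean(is.na(assay(object, "lc50"))), object@zLow))
  cat("  subtypes:", paste(levels(factor(cd$subtype)), collapse = ", "), "\n")
})
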