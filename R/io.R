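# Cohort file schema: one CSV row per patient with columns
#   patient_id, age, gender (Male/Female), wbc, subtype, protocol,
#   mrd_day15, mrd_day42, lc50_<drug> ...
# MRD columns are on the percent scale; a value below the detection limit is
# written as the literal token "<0.01" (numeric values below the limit are
# also treated as censored on read). WBC is stored raw and log10-transformed
# on load.

#' Read a cohort CSV
#'
#' Parses the documented cohort schema into an [MRDCohort-class]. Censoring
#' indicators are derived from the detection limit (default 0.01%): a literal
#' `"<0.01"` token or a numeric value below the limit yields `delta = 0` with
#' the stored value at the log10 bound. Ph-like subtype variants (labels
#' starting with `"Ph-like"`) are merged into a single `Ph-like` level, and
#' subtypes with fewer than `subtypeMin` patients are merged into `"Other"`.
#'
#' @param path CSV file path.
#' @param subtypeMin minimum patients per subtype before merging into
#'   `"Other"` (default 10).
#' @param detectionLimit MRD detection limit on the percent scale (default
#'   0.01, i.e. `zLow = -2`).
#' @param vocabulary optional character vector of allowed subtype labels
#'   (checked before Ph-like merging); unknown labels raise an error naming
#'   the offending rows.
#' @return an [MRDCohort-class].
#' @export
readCohort <- function(path, subtypeMin = 10L, detectionLimit = 0.01,
                       vocabulary = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("patient_id", "age", "gender", "wbc", "subtype", "protocol",
            "mrd_day15", "mrd_day42")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("validation error: missing column(s): ", paste(miss, collapse = ", "))
  lcCols <- grep("^lc50_", colnames(df), value = TRUE)
  if (!length(lcCols))
    stop("validation error: no lc50_* columns found")
  bad <- which(!df$gender %in% c("Male", "Female"))
  if (length(bad))
    stop("validation error: column 'gender' invalid in row(s) ",
         paste(bad, collapse = ", "))
  wbc <- suppressWarnings(as.numeric(df$wbc))
  bad <- which(is.na(wbc) | wbc <= 0)
  if (length(bad))
    stop("validation error: column 'wbc' must be positive numeric; row(s) ",
         paste(bad, collapse = ", "))
  if (!is.null(vocabulary)) {
    bad <- which(!df$subtype %in% vocabulary)
    if (length(bad))
      stop("validation error: unknown subtype label in row(s) ",
           paste(bad, collapse = ", "))
  }

  parseMRD <- function(x, column) {
    x <- trimws(as.character(x))
    censTok <- x == paste0("<", format(detectionLimit, trim = TRUE))
    val <- suppressWarnings(as.numeric(x))
    bad <- which(!censTok & (is.na(val) | val < 0))
    if (length(bad))
      stop("validation error: column '", column,
           "' non-numeric MRD in row(s) ", paste(bad, collapse = ", "))
    cens <- censTok | (!is.na(val) & val < detectionLimit)
    zlow <- log10(detectionLimit)
    z <- ifelse(cens, zlow, log10(val))
    list(z = z, delta = as.integer(!cens))
  }
  m1 <- parseMRD(df$mrd_day15, "mrd_day15")
  m2 <- parseMRD(df$mrd_day42, "mrd_day42")

  subtype <- df$subtype
  subtype[startsWith(subtype, "Ph-like")] <- "Ph-like"
  counts <- table(subtype)
  small <- names(counts)[counts < subtypeMin]
  subtype[subtype %in% small] <- "Other"

  covariates <- data.frame(
    age = as.numeric(df$age),
    male = as.integer(df$gender == "Male"),
    log10WBC = log10(wbc),
    subtype = subtype,
    protocol = df$protocol,
    stringsAsFactors = FALSE)
  mrd <- data.frame(z1 = m1$z, delta1 = m1$delta,
                    z2 = m2$z, delta2 = m2$delta)
  lc50 <- as.matrix(df[, lcCols, drop = FALSE])
  colnames(lc50) <- sub("^lc50_", "", lcCols)
  MRDCohort(covariates, mrd, lc50, zLow = log10(detectionLimit),
            patientID = as.character(df$patient_id))
}

#' Write a cohort CSV
#'
#' Inverse of [readCohort()]: MRD is written on the percent scale with
#' censored entries as the `"<0.01"` token, WBC and gender are mapped back to
#' their file representations.
#'
#' @param cohort an [MRDCohort-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  cd <- colData(cohort)
  limit <- 10^zLow(cohort)
  tok <- paste0("<", format(limit, trim = TRUE))
  mrdOut <- function(z, delta) ifelse(delta == 1L, as.character(10^z), tok)
  lc <- lc50Matrix(cohort)
  df <- data.frame(
    patient_id = rownames(cd),
    age = cd$age,
    gender = ifelse(cd$male == 1L, "Male", "Female"),
    wbc = 10^cd$log10WBC,
    subtype = as.character(cd$subtype),
    protocol = as.character(cd$protocol),
    mrd_day15 = mrdOut(cd$z1, cd$delta1),
    mrd_day42 = mrdOut(cd$z2, cd$delta2),
    check.names = FALSE, stringsAsFactors = FALSE)
  for (j in colnames(lc)) df[[paste0("lc50_", j)]] <- lc[, j]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
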