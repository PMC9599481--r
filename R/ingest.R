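# Quantifiability filtering and imputation.
#
# Features are removed when their missing fraction across samples exceeds 30%
# or their QC coefficient of variation exceeds 30% (both strictly: boundary
# values are retained). Remaining missing cells are imputed with one half of
# the per-feature minimum observed value.

#' Per-feature coefficient of variation from QC replicates
#'
#' CV = sample standard deviation / mean, computed per feature over technical
#' replicates, missing values excluded. Features whose CV is undefined (mean
#' zero, or fewer than 2 observed replicates) get `NA` and are listed in the
#' `"undefined"` attribute.
#'
#' @param qc_table a `lpn_quant` of QC replicates (>= 3 rows).
#' @return Named numeric vector of CV fractions, attribute `undefined`.
#' @export
compute_cv <- function(qc_table) {
  stopifnot(inherits(qc_table, "lpn_quant"))
  if (nrow(qc_table$values) < 3L) stop("need >= 3 QC replicates to estimate CVs")
  v <- qc_table$values
  m <- apply(v, 2, mean, na.rm = TRUE)
  s <- apply(v, 2, stats::sd, na.rm = TRUE)
  nobs <- colSums(!is.na(v))
  cv <- s / m
  bad <- !is.finite(cv) | nobs < 2L | m == 0
  cv[bad] <- NA_real_
  structure(cv, undefined = names(cv)[bad])
}

#' Per-class CVs of class total concentrations (reporting aid)
#'
#' The filtering rule is per-feature, but class-level CVs of summed class
#' concentrations are also of interest for reporting.
#' @param qc_table a `lpn_quant` of QC replicates.
#' @export
compute_class_cv <- function(qc_table) {
  tot <- class_totals(qc_table)
  apply(tot, 2, function(x) stats::sd(x, na.rm = TRUE) / mean(x, na.rm = TRUE))
}

#' QC summary: CV, missing fraction and keep flag per feature
#'
#' @param table cohort `lpn_quant` (missingness is computed across all its
#'   samples).
#' @param cv named CV vector from [compute_cv()] (features absent from it are
#'   treated as CV-undefined).
#' @param max_missing,max_cv retention thresholds; removal is strict
#'   (`> max`), so boundary features are kept. CV-undefined features are not
#'   kept.
#' @return data.frame(feature_id, cv, missing_fraction, kept).
#' @export
qc_summary <- function(table, cv, max_missing = 0.30, max_cv = 0.30) {
  stopifnot(inherits(table, "lpn_quant"), is_fraction(max_missing), is_fraction(max_cv))
  feats <- colnames(table$values)
  mf <- colMeans(is.na(table$values))
  cvv <- unname(cv[feats])
  kept <- mf <= max_missing & !is.na(cvv) & cvv <= max_cv
  data.frame(feature_id = feats, cv = cvv, missing_fraction = unname(mf),
             kept = kept, stringsAsFactors = FALSE)
}

#' Apply the quantifiability filter
#'
#' @param table cohort `lpn_quant`.
#' @param qc either a named CV vector ([compute_cv()]) or a [qc_summary()]
#'   data.frame covering all features.
#' @inheritParams qc_summary
#' @return list(`table` = filtered `lpn_quant`, `qc` = the summary with keep
#'   flags; removed features are logged via message).
#' @export
filter_features <- function(table, qc, max_missing = 0.30, max_cv = 0.30) {
  if (is.data.frame(qc)) qc <- stats::setNames(qc$cv, qc$feature_id)
  absent <- setdiff(colnames(table$values), names(qc))
  if (length(absent)) stop("QC CVs missing for features: ", paste(absent, collapse = ", "))
  summ <- qc_summary(table, qc, max_missing, max_cv)
  removed <- summ$feature_id[!summ$kept]
  if (length(removed))
    lpn_log("ingest", sprintf("removed=%d/%d features (missing>%.2f or CV>%.2f)",
                              length(removed), nrow(summ), max_missing, max_cv))
  out <- subset_quant(table, features = summ$feature_id[summ$kept])
  list(table = out, qc = summ)
}

#' Half-minimum imputation
#'
#' Each missing cell of feature f is set to `min(observed f) / 2`; observed
#' cells (including exact zeros, which count as observed) are untouched.
#'
#' @param table a `lpn_quant`; every feature must have at least one observed
#'   value (all-missing features should have been filtered).
#' @export
impute_half_min <- function(table) {
  stopifnot(inherits(table, "lpn_quant"))
  v <- table$values
  allmiss <- colSums(!is.na(v)) == 0L
  if (any(allmiss)) stop("feature(s) with zero observed values (filter first): ",
                         paste(colnames(v)[allmiss], collapse = ", "))
  for (j in seq_len(ncol(v))) {
    na <- is.na(v[, j])
    if (any(na)) v[na, j] <- min(v[, j], na.rm = TRUE) / 2
  }
  quant_table(v, table$feature_meta)
}
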