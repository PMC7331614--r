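#' Intensity preprocessing and per-patient metabolite z-scores
#'
#' Feature tables are numeric matrices (features x samples, `NA` =
#' not detected) from a single biofluid. The preprocessing chain mirrors
#' standard untargeted-metabolomics practice: prevalence filtering,
#' per-sample median scaling, minimum-value imputation, log transform,
#' linear baseline normalization, then a z-score per feature for one
#' patient against the full sample set.
#'
#' @name abundance
#' @keywords internal
NULL

#' Prevalence filter, median scaling and minimum imputation
#'
#' Removes features detected in fewer than `min_prevalence` of samples
#' (boundary inclusive: exactly 10% is kept), scales each sample so its
#' median detected intensity equals the grand median (median of sample
#' medians), and imputes remaining missing values with the feature's
#' minimum detected (scaled) intensity. Features detected in no sample are
#' dropped with a warning.
#'
#' @param mat Numeric matrix, features x samples, `NA` for not detected.
#' @param min_prevalence Minimum detection fraction (default 0.10).
#' @return The filtered, scaled, imputed matrix (no `NA`s).
#' @export
preprocess_features <- function(mat, min_prevalence = 0.10) {
  stopifnot(is.matrix(mat), min_prevalence > 0, min_prevalence <= 1)
  detected <- !is.na(mat)
  none <- rowSums(detected) == 0
  if (any(none)) {
    warning(sum(none), " feature(s) detected in no sample removed")
    mat <- mat[!none, , drop = FALSE]
    detected <- detected[!none, , drop = FALSE]
  }
  prev <- rowMeans(detected)
  mat <- mat[prev >= min_prevalence, , drop = FALSE]
  if (!nrow(mat)) stop("no features pass the prevalence filter")

  med <- apply(mat, 2, stats::median, na.rm = TRUE)
  if (any(!is.finite(med) | med <= 0)) stop("sample with non-positive median intensity")
  grand <- stats::median(med)
  mat <- sweep(mat, 2, grand / med, "*")

  feat_min <- apply(mat, 1, min, na.rm = TRUE)
  idx <- which(is.na(mat), arr.ind = TRUE)
  if (nrow(idx)) mat[idx] <- feat_min[idx[, 1]]
  mat
}

#' Linear baseline normalization
#'
#' Treats every (log-scale) sample as a scalar multiple of a baseline
#' profile: the baseline is the per-feature median across samples,
#' \eqn{\beta_j} = mean(baseline) / mean(sample j), and each sample is
#' multiplied by its \eqn{\beta_j}. After normalization every sample mean
#' equals the baseline mean, so the operation is idempotent.
#'
#' @param mat Log-transformed intensity matrix (features x samples).
#' @return The normalized matrix, with the baseline attached as
#'   `attr(, "baseline")` and the scaling factors as `attr(, "beta")`.
#' @export
linear_baseline_normalize <- function(mat) {
  stopifnot(is.matrix(mat), !anyNA(mat))
  baseline <- apply(mat, 1, stats::median)
  sample_means <- colMeans(mat)
  if (any(sample_means == 0)) stop("sample with zero mean intensity")
  beta <- mean(baseline) / sample_means
  out <- sweep(mat, 2, beta, "*")
  attr(out, "baseline") <- baseline
  attr(out, "beta") <- beta
  out
}

#' Per-patient feature z-scores
#'
#' For one patient column, computes z = (x_patient - mean) / sd per
#' feature, with mean and sd taken over all samples in the table (patient
#' included by default; sample sd, n-1 denominator). Constant features
#' (zero sd) are dropped with a warning.
#'
#' @param mat Numeric matrix, features x samples, no `NA`s.
#' @param patient Column name of the patient sample.
#' @param leave_patient_out If `TRUE`, the reference mean/sd exclude the
#'   patient column.
#' @return Data frame with columns `id` (feature/metabolite ID) and `z`.
#' @export
zscore_patient <- function(mat, patient, leave_patient_out = FALSE) {
  stopifnot(is.matrix(mat), patient %in% colnames(mat), ncol(mat) >= 3)
  ref <- if (leave_patient_out) {
    mat[, setdiff(colnames(mat), patient), drop = FALSE]
  } else {
    mat
  }
  mu <- rowMeans(ref)
  sdv <- apply(ref, 1, stats::sd)
  bad <- sdv == 0 | !is.finite(sdv)
  if (any(bad)) {
    warning(sum(bad), " constant feature(s) dropped (undefined z-score)")
  }
  keep <- !bad
  data.frame(id = rownames(mat)[keep],
             z = (mat[keep, patient] - mu[keep]) / sdv[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call differentially abundant metabolites (DAMs)
#'
#' A metabolite is differentially abundant when |z| >= threshold
#' (inclusive; default 2, i.e. two control SDs from the control mean). The
#' direction (sign of z) is recorded.
#'
#' @param z Data frame with columns `id` and `z` (e.g. from
#'   [zscore_patient()]), or a named numeric vector.
#' @param threshold Absolute z-score cut-off, > 0 (default 2).
#' @return Data frame `id`, `z`, `direction` (+1/-1) for the DAM subset,
#'   with the threshold attached as an attribute.
#' @export
call_dams <- function(z, threshold = 2) {
  stopifnot(threshold > 0)
  if (!is.data.frame(z)) {
    z <- data.frame(id = names(z), z = unname(z), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "z") %in% names(z)), all(is.finite(z$z)))
  out <- z[abs(z$z) >= threshold, c("id", "z"), drop = FALSE]
  out$direction <- sign(out$z)
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}

#' Merge z-score tables from multiple ionization modes
#'
#' Positive- and negative-mode results are combined before enrichment;
#' metabolites observed in both modes keep the z-score of largest
#' magnitude.
#'
#' @param ... Data frames with columns `id` and `z`.
#' @return A single deduplicated z-score data frame.
#' @export
merge_mode_zscores <- function(...) {
  tabs <- list(...)
  all <- do.call(rbind, lapply(tabs, function(t) t[, c("id", "z")]))
  all <- all[order(all$id, -abs(all$z)), ]
  out <- all[!duplicated(all$id), ]
  rownames(out) <- NULL
  out
}

#' Map feature-level z-scores onto metabolite identities
#'
#' Every retained metabolite identity of a feature inherits that feature's
#' z-score; when several features map to one metabolite the z of largest
#' magnitude is kept.
#'
#' @param feature_z Data frame `id`, `z` at the feature level.
#' @param annotations Match table from [match_features()].
#' @return Data frame `id`, `z` at the metabolite level.
#' @export
feature_z_to_metabolites <- function(feature_z, annotations) {
  m <- merge(annotations, feature_z, by.x = "feature_id", by.y = "id")
  merge_mode_zscores(data.frame(id = m$metabolite_id, z = m$z,
                                stringsAsFactors = FALSE))
}
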