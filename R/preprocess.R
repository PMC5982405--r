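#' Total-ion-current / summed-abundance normalization
#'
#' Rescales each sample so its summed ion abundance equals the across-sample
#' mean of the raw row sums.  `mode = "tic"` is the normalization applied to
#' the full feature table before filtering; `mode = "summed_abundance"` is
#' the same row-sum equalization applied again after filtering, on the
#' retained feature set only — the two modes share the formula and differ
#' only in where they sit in the pipeline.  Using the mean raw row sum as
#' the common target keeps the data on its original scale (any common
#' constant is equivalent up to a global factor).
#'
#' The operation is idempotent: normalizing an already-normalized table is
#' the identity up to floating-point error.
#'
#' @param ds a [cohort_dataset()] with non-negative abundances.
#' @param mode `"tic"` or `"summed_abundance"` (same formula; recorded in
#'   the returned dataset's provenance attribute).
#' @return The dataset with rescaled abundances.
#' @export
normalize_abundance <- function(ds, mode = c("tic", "summed_abundance")) {
  mode <- match.arg(mode)
  rs <- rowSums(ds$abundance)
  if (any(rs <= 0)) {
    bad <- rownames(ds$abundance)[which(rs <= 0)[1]]
    plsvip_error(sprintf("sample %s has zero total abundance", bad),
                 "plsvip_degenerate_sample_error")
  }
  target <- mean(rs)
  ds$abundance <- ds$abundance * (target / rs)
  attr(ds, "normalization") <- mode
  ds
}

#' Blank, abundance-floor and retention-time feature filtering
#'
#' Removes, in this order: (1) features whose abundance in the blank
#' injection is at least `blank_fraction` of their mean abundance across
#' study samples (contaminants); (2) features whose maximum sample abundance
#' is below `min_abundance` (too faint for a reliable precursor signal);
#' (3) features eluting outside the retention-time window where lipids are
#' expected.  Each removed feature appears exactly once in the removal log,
#' under the first rule that caught it.
#'
#' @param ds a [cohort_dataset()].
#' @param blank optional named numeric vector of blank-injection abundances
#'   (one per feature, names = feature ids); `NULL` skips the blank rule.
#' @param blank_fraction blank-to-sample abundance ratio at or above which a
#'   feature counts as present in the blank (default 0.5).
#' @param min_abundance abundance floor; 0 disables the rule.
#' @param rt_window numeric `c(lo, hi)` in minutes, `lo < hi`.
#' @return List with `dataset` (the filtered [cohort_dataset()]) and
#'   `removal_log`, a data frame with columns `feature_id`, `rule`
#'   (`"blank"`, `"abundance"`, or `"rt"`) and `value` (the offending
#'   quantity).
#' @export
filter_features <- function(ds, blank = NULL, blank_fraction = 0.5,
                            min_abundance = 0, rt_window = c(0, Inf)) {
  if (length(rt_window) != 2 || !(rt_window[1] < rt_window[2]))
    plsvip_error("rt_window must be c(lo, hi) with lo < hi",
                 "plsvip_config_error")
  fid <- ds$features$feature_id
  removed <- character(0)
  log_rows <- list()
  mark <- function(ids, rule, values) {
    ids <- setdiff(ids, removed)
    if (!length(ids)) return(invisible())
    removed <<- c(removed, ids)
    log_rows[[length(log_rows) + 1]] <<- data.frame(
      feature_id = ids, rule = rule, value = unname(values[ids]),
      stringsAsFactors = FALSE)
  }
  if (!is.null(blank)) {
    blank <- blank[fid]
    mean_ab <- colMeans(ds$abundance)
    ratio <- stats::setNames(as.numeric(blank) / mean_ab, fid)
    mark(fid[!is.na(ratio) & ratio >= blank_fraction], "blank", ratio)
  }
  if (min_abundance > 0) {
    mx <- stats::setNames(apply(ds$abundance, 2, max), fid)
    mark(fid[mx < min_abundance], "abundance", mx)
  }
  rt <- stats::setNames(ds$features$rt, fid)
  out_rt <- fid[!is.na(rt) & (rt < rt_window[1] | rt > rt_window[2])]
  mark(out_rt, "rt", rt)

  keep <- setdiff(fid, removed)
  if (!length(keep))
    plsvip_error("all features removed by filtering", "plsvip_empty_table_error")
  removal_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(feature_id = character(), rule = character(),
               value = numeric(), stringsAsFactors = FALSE)
  rownames(removal_log) <- NULL
  list(dataset = subset_features(ds, keep), removal_log = removal_log)
}

#' Autoscale a feature matrix
#'
#' Centers every feature column to mean zero and scales it to unit sample
#' standard deviation (n - 1 denominator) — the scaling applied before all
#' multivariate modeling.  The estimated parameters are returned so held-out
#' samples can be projected with calibration-set scaling (no test-set
#' leakage inside cross-validation).
#'
#' @param x numeric matrix, samples in rows.
#' @return List with `x` (the scaled matrix), `center` and `scale`
#'   (per-column mean and standard deviation).
#' @export
autoscale <- function(x) {
  x <- as.matrix(x)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  zero <- scale < 1e-12
  if (any(zero))
    plsvip_error(sprintf("zero-variance feature(s): %s",
                         paste(colnames(x)[zero] %||%
                                 which(zero), collapse = ", ")),
                 "plsvip_zero_variance_error")
  list(x = sweep(sweep(x, 2, center), 2, scale, `/`),
       center = center, scale = scale)
}

#' Apply stored autoscaling parameters to new samples
#' @param x numeric matrix, samples in rows (same feature columns as the
#'   calibration set the parameters came from).
#' @param center,scale per-column parameters from [autoscale()].
#' @return The scaled matrix.
#' @export
apply_scaling <- function(x, center, scale) {
  sweep(sweep(as.matrix(x), 2, center), 2, scale, `/`)
}

#' Invert autoscaling
#' @inheritParams apply_scaling
#' @return The matrix on its original scale.
#' @export
invert_scaling <- function(x, center, scale) {
  sweep(sweep(as.matrix(x), 2, scale, `*`), 2, center, `+`)
}

# Tolerant scaler for use inside cross-validation folds: a column that is
# constant in a fold's training portion gets scale 1 (it then contributes
# zeros, which is harmless) instead of aborting the whole fold.
.scale_train <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale < 1e-12] <- 1
  list(x = sweep(sweep(x, 2, center), 2, scale, `/`),
       center = center, scale = scale)
}
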