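#' Configuration for CV2 stability selection
#'
#' @param n_iterations number of outer calibration/test splits (the study
#'   design uses 500; smaller values are useful for exploration).
#' @param test_count number of held-out samples B per split; the
#'   calibration set is the complement (A = I - B).
#' @param freq_threshold selection-frequency cutoff in (0, 1] defining the
#'   stable set (0.80 for larger arms, 0.95 for the smallest in the study
#'   design).
#' @param vip_grid increasing vector of VIP thresholds scanned by the
#'   iterative pruner.  Default `seq(0.8, 2.5, by = 0.1)`: VIP = 1 is the
#'   conventional relevance point, and the grid brackets it on both sides.
#' @param rmsecv_tolerance relative RMSECV worsening tolerated before the
#'   threshold scan stops (default 0.01).
#' @param k_folds inner venetian-blind fold count (default 4).
#' @param a_max largest latent-variable count scanned; `NULL` means
#'   `min(A - 2, 10)`.
#' @param recompute_vip if `TRUE`, VIP scores are recomputed from the
#'   refitted model after each pruning round; the default computes them
#'   once per split, on the full calibration model.
#' @param stop_rule `"best_accepted"` (default) evaluates the whole
#'   threshold grid and returns the highest threshold whose RMSECV stays
#'   within tolerance of the best value seen, so a single noisy RMSECV
#'   bump cannot end the pruning prematurely; `"first_worsening"` stops
#'   the scan at the first threshold that worsens RMSECV beyond
#'   tolerance.
#' @param seed master seed; per-iteration seeds are derived from it by a
#'   fixed counter stream so iterations are individually reproducible.
#' @return A list of class `cv2_config`.
#' @export
cv2_config <- function(n_iterations = 500, test_count = 5,
                       freq_threshold = 0.8,
                       vip_grid = seq(0.8, 2.5, by = 0.1),
                       rmsecv_tolerance = 0.01, k_folds = 4, a_max = NULL,
                       recompute_vip = FALSE,
                       stop_rule = c("best_accepted", "first_worsening"),
                       seed = 1) {
  stop_rule <- match.arg(stop_rule)
  if (n_iterations < 1)
    plsvip_error("n_iterations must be >= 1", "plsvip_config_error")
  if (freq_threshold <= 0 || freq_threshold > 1)
    plsvip_error("freq_threshold must be in (0, 1]", "plsvip_config_error")
  if (test_count < 2)
    plsvip_error("test_count must be >= 2 so both classes can be held out",
                 "plsvip_config_error")
  if (is.unsorted(vip_grid))
    plsvip_error("vip_grid must be increasing", "plsvip_config_error")
  structure(list(n_iterations = n_iterations, test_count = test_count,
                 freq_threshold = freq_threshold, vip_grid = vip_grid,
                 rmsecv_tolerance = rmsecv_tolerance, k_folds = k_folds,
                 a_max = a_max, recompute_vip = recompute_vip,
                 stop_rule = stop_rule, seed = seed),
            class = "cv2_config")
}

# Deterministic per-iteration seed stream below 2^31.
.iter_seed <- function(master, i) (master + 99991 * i) %% 2147483647L

#' Stratified random calibration/test split
#'
#' Draws B test samples so that the per-class test counts are proportional
#' to the full dataset's class balance (largest-remainder rounding, at
#' least one sample per class when `B >= 2`); the calibration set is the
#' complement.  Uses the current RNG state.
#'
#' @param label factor/character class labels for all samples.
#' @param B test-set size, `2 <= B < length(label)`.
#' @return List with integer index vectors `calibration` and `test`.
#' @export
stratified_split <- function(label, B) {
  label <- as.character(label)
  I <- length(label)
  if (B >= I) plsvip_error("B must be < sample count", "plsvip_config_error")
  classes <- unique(label)
  n_c <- vapply(classes, function(cl) sum(label == cl), numeric(1))
  raw <- B * n_c / I
  take <- floor(raw)
  rem <- B - sum(take)
  if (rem > 0) {
    ord <- order(raw - take, decreasing = TRUE)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1
  }
  if (B >= 2 && any(take == 0)) {
    # move one slot from the best-represented class
    donor <- which.max(take)
    take[take == 0][1] <- 1
    take[donor] <- take[donor] - 1
  }
  if (any(take >= n_c))
    plsvip_error("split leaves a class empty in the calibration set",
                 "plsvip_stratification_error")
  test <- integer(0)
  for (ci in seq_along(classes))
    test <- c(test, sample(which(label == classes[ci]), take[ci]))
  test <- sort(test)
  cal <- setdiff(seq_len(I), test)
  if (length(unique(label[cal])) < 2 ||
      any(vapply(classes, function(cl) sum(label[cal] == cl), numeric(1)) < 2))
    plsvip_error("calibration set does not retain >= 2 samples per class",
                 "plsvip_stratification_error")
  list(calibration = cal, test = test)
}

#' Iterative VIP-threshold pruning against RMSECV
#'
#' Fits a full PLS-DA model on the calibration samples (latent-variable
#' count from the inner venetian-blind RMSECV curve), computes VIP scores,
#' then scans the VIP threshold grid upward.  At each threshold the model is
#' refitted on the retained features with the latent-variable count
#' re-optimized, and its RMSECV recorded.  A threshold is accepted when its
#' RMSECV does not worsen by more than `rmsecv_tolerance` (relative) over
#' the best value seen so far; the selection at the last accepted threshold
#' is returned.  Under the default `stop_rule = "best_accepted"` the whole
#' grid is evaluated (the scan only ends early when fewer than two features
#' would remain), so the pruning reaches the point below which the models
#' do not increase their RMSECV even if one intermediate threshold shows a
#' noisy bump; `"first_worsening"` instead stops at the first rejected
#' threshold.
#'
#' @param x_cal calibration feature matrix on its raw (pre-autoscaling)
#'   scale; autoscaling happens inside, per fold and for the final model.
#' @param y_cal class codes or labels.
#' @param cfg a [cv2_config()].
#' @return List: `features` (selected feature names), `threshold` (last
#'   accepted VIP threshold; 0 means no pruning survived), `model` (final
#'   `pls_model` carrying its calibration scaling), `rmsecv`, `n_lv`, and
#'   `path` (data frame of the scanned thresholds).
#' @export
iterative_vip_prune <- function(x_cal, y_cal, cfg) {
  x_cal <- as.matrix(x_cal)
  if (is.null(colnames(x_cal)))
    colnames(x_cal) <- paste0("V", seq_len(ncol(x_cal)))
  if (is.factor(y_cal) || is.character(y_cal)) y_cal <- class_codes(y_cal)

  fit_at <- function(cols) {
    curve <- rmsecv_curve(x_cal[, cols, drop = FALSE], y_cal,
                          a_max = cfg$a_max, k = cfg$k_folds)
    sc <- .scale_train(x_cal[, cols, drop = FALSE])
    model <- fit_pls(sc$x, y_cal, n_lv = curve$n_lv)
    model <- set_model_scaling(model, sc$center, sc$scale)
    list(model = model, rmsecv = unname(curve$rmsecv[curve$n_lv]),
         n_lv = curve$n_lv)
  }

  all_cols <- colnames(x_cal)
  full <- fit_at(all_cols)
  vip <- vip_scores(full$model)
  accepted <- list(features = all_cols, threshold = 0, model = full$model,
                   rmsecv = full$rmsecv, n_lv = full$n_lv)
  best <- full$rmsecv
  path <- list(data.frame(threshold = 0, n_features = length(all_cols),
                          rmsecv = full$rmsecv, n_lv = full$n_lv,
                          accepted = TRUE))
  prev_sel <- all_cols
  prev_res <- full
  for (gi in seq_along(cfg$vip_grid)) {
    t_vip <- cfg$vip_grid[gi]
    sel <- names(vip)[vip >= t_vip]
    if (length(sel) < 2) {
      if (gi == 1)
        plsvip_error(
          "first VIP grid threshold leaves fewer than 2 features",
          "plsvip_grid_error")
      break
    }
    if (identical(sel, prev_sel)) {
      res <- prev_res   # same feature set: RMSECV unchanged by construction
    } else {
      res <- fit_at(sel)
    }
    ok <- res$rmsecv <= best * (1 + cfg$rmsecv_tolerance) + 1e-12
    path[[length(path) + 1]] <- data.frame(
      threshold = t_vip, n_features = length(sel), rmsecv = res$rmsecv,
      n_lv = res$n_lv, accepted = ok)
    if (!ok && cfg$stop_rule == "first_worsening") break
    if (ok) {
      accepted <- list(features = sel, threshold = t_vip, model = res$model,
                       rmsecv = res$rmsecv, n_lv = res$n_lv)
      best <- min(best, res$rmsecv)
      if (cfg$recompute_vip) vip <- vip_scores(res$model)
    }
    prev_sel <- sel
    prev_res <- res
  }
  accepted$path <- do.call(rbind, path)
  accepted
}

#' One CV2 iteration: split, prune, test
#'
#' Runs a single outer split of the double cross-validation: a stratified
#' calibration/test split, VIP-threshold pruning with inner venetian-blind
#' CV on the calibration samples only, then classification of the held-out
#' test samples with the final pruned model.  Test samples never inform
#' selection or scaling.
#'
#' @param ds a preprocessed, labeled [cohort_dataset()].
#' @param cfg a [cv2_config()].
#' @param seed optional integer seed for this iteration's RNG.
#' @return An object of class `cv2_iteration`: sample-id split, chosen
#'   latent-variable count, VIP threshold, selected feature ids, final
#'   RMSECV, test misclassification count, and test size.
#' @export
run_cv2_iteration <- function(ds, cfg, seed = NULL) {
  run <- function() {
    split <- stratified_split(ds$label, cfg$test_count)
    x_cal <- ds$abundance[split$calibration, , drop = FALSE]
    y_cal <- class_codes(ds$label[split$calibration])
    pruned <- iterative_vip_prune(x_cal, y_cal, cfg)
    x_test <- ds$abundance[split$test, pruned$features, drop = FALSE]
    res <- classify_samples(pruned$model, x_test, ds$label[split$test])
    structure(list(
      calibration_ids = rownames(ds$abundance)[split$calibration],
      test_ids = rownames(ds$abundance)[split$test],
      n_lv = pruned$n_lv, threshold = pruned$threshold,
      selected = pruned$features, rmsecv = pruned$rmsecv,
      misclassified = res$misclassified, test_size = length(split$test)),
      class = "cv2_iteration")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Repeated CV2 stability selection
#'
#' Repeats [run_cv2_iteration()] `n_iterations` times with a seed-derived
#' stream, tallies how often each feature is selected, and retains the
#' stable set of features whose selection frequency reaches
#' `freq_threshold`.  The summary aggregates the per-iteration model
#' diagnostics (latent variables, RMSECV, test misclassification rate) in
#' the layout conventional for reporting this procedure.
#'
#' @param ds a preprocessed, labeled [cohort_dataset()].
#' @param cfg a [cv2_config()].
#' @return An object of class `stability_summary`: `frequency` (named
#'   per-feature selection frequency), `stable_set` (feature ids at or
#'   above the threshold), `freq_threshold`, means and sds of `n_lv` and
#'   `rmsecv`, mean `misclassified_pct`, `n_iterations`, and the list of
#'   `iterations` records.
#' @export
run_stability_selection <- function(ds, cfg) {
  stopifnot(inherits(cfg, "cv2_config"))
  iters <- vector("list", cfg$n_iterations)
  for (i in seq_len(cfg$n_iterations))
    iters[[i]] <- run_cv2_iteration(ds, cfg, seed = .iter_seed(cfg$seed, i))
  fid <- ds$features$feature_id
  counts <- stats::setNames(numeric(length(fid)), fid)
  for (it in iters) counts[it$selected] <- counts[it$selected] + 1
  freq <- counts / cfg$n_iterations
  n_lv <- vapply(iters, `[[`, numeric(1), "n_lv")
  rmsecv <- vapply(iters, `[[`, numeric(1), "rmsecv")
  mis_pct <- vapply(iters, function(it)
    100 * it$misclassified / it$test_size, numeric(1))
  structure(list(
    frequency = freq,
    stable_set = fid[freq >= cfg$freq_threshold],
    freq_threshold = cfg$freq_threshold,
    n_lv_mean = mean(n_lv), n_lv_sd = stats::sd(n_lv),
    rmsecv_mean = mean(rmsecv), rmsecv_sd = stats::sd(rmsecv),
    misclassified_pct_mean = mean(mis_pct),
    misclassified_pct_sd = stats::sd(mis_pct),
    n_iterations = cfg$n_iterations,
    iterations = iters),
    class = "stability_summary")
}

#' @export
print.stability_summary <- function(x, ...) {
  sd_or_0 <- function(v) if (is.na(v)) 0 else v
  cat(sprintf("CV2 stability selection over %d iterations\n", x$n_iterations))
  cat(sprintf("  # of latent variables  %.2f (%.2f)\n",
              x$n_lv_mean, sd_or_0(x$n_lv_sd)))
  cat(sprintf("  RMSECV                 %.3f (%.3f)\n",
              x$rmsecv_mean, sd_or_0(x$rmsecv_sd)))
  cat(sprintf("  Misclassified          %.1f (%.1f) %%\n",
              x$misclassified_pct_mean, sd_or_0(x$misclassified_pct_sd)))
  cat(sprintf("  M/Z selected           %d (frequency >= %.0f%%)\n",
              length(x$stable_set), 100 * x$freq_threshold))
  invisible(x)
}
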