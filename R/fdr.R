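#' One-way ANOVA F statistic for a two-group comparison
#'
#' `F = [SSB / (g - 1)] / [SSW / (I - g)]` with g groups; for two groups it
#' equals the square of the pooled-variance two-sample t statistic.  A
#' comparison with zero within-group variance but nonzero between-group
#' variance returns `Inf` (a sentinel that ranks above every finite F);
#' zero variance both between and within returns 0.
#'
#' @param values numeric vector of per-sample feature values.
#' @param labels group labels (two groups, each with >= 2 members).
#' @return The F statistic (possibly `Inf`).
#' @export
anova_f <- function(values, labels) {
  drop(anova_f_matrix(matrix(values, ncol = 1), labels))
}

#' Column-wise one-way ANOVA F statistics
#'
#' Vectorized version of [anova_f()] over the columns of a matrix.
#'
#' @param x numeric matrix, samples in rows.
#' @param labels group labels for the rows.
#' @return Named numeric vector of F statistics, one per column.
#' @export
anova_f_matrix <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  groups <- unique(labels)
  g <- length(groups)
  I <- nrow(x)
  if (g < 2) plsvip_error("need at least two groups", "plsvip_config_error")
  if (any(vapply(groups, function(gr) sum(labels == gr), numeric(1)) < 2))
    plsvip_error("every group needs >= 2 members", "plsvip_config_error")
  grand <- colMeans(x)
  ssb <- numeric(ncol(x)); ssw <- numeric(ncol(x))
  for (gr in groups) {
    rows <- labels == gr
    m <- colMeans(x[rows, , drop = FALSE])
    ssb <- ssb + sum(rows) * (m - grand)^2
    ssw <- ssw + colSums(sweep(x[rows, , drop = FALSE], 2, m)^2)
  }
  f <- (ssb / (g - 1)) / (ssw / (I - g))
  f[ssw == 0 & ssb > 0] <- Inf
  f[ssw == 0 & ssb == 0] <- 0
  stats::setNames(f, colnames(x))
}

#' Permutation-null FDR estimation for per-feature F statistics
#'
#' Builds a null F distribution from comparisons that cannot carry class
#' signal: within each true class, the samples are randomly bipartitioned
#' into two pseudo-groups and the per-feature F statistic is computed for
#' that pseudo-comparison.  Nulls are pooled over both classes and
#' `n_null` draws.  For each feature, the estimated FDR is the expected
#' number of null features at or above its observed F (per comparison)
#' divided by the observed number of features at or above it, capped at 1
#' and made monotone non-increasing in F (step-up over the observed F
#' order).
#'
#' @param x feature matrix (samples x features), typically restricted to
#'   the stable set from [run_stability_selection()].
#' @param labels true class labels (each class needs >= 4 samples so it can
#'   be split into two pseudo-groups of >= 2).
#' @param n_null number of random bipartitions per class (default 500).
#'   With `exact = TRUE` and class sizes <= 12, all distinct bipartitions
#'   are enumerated instead.
#' @param confidence confidence level for the reported null-F threshold
#'   (default 0.99).
#' @param fdr_threshold FDR cutoff defining the final panel (default 0.05).
#' @param exact enumerate all bipartitions instead of sampling.
#' @param seed optional seed for the random bipartitions.
#' @return An object of class `ftest_report`: `f` (named observed F),
#'   `fdr` (named estimates), `panel` (feature ids with FDR at or below
#'   the cutoff), `null_f` (pooled null sample), `null_threshold` (null-F
#'   quantile at `confidence`), `n_comparisons`.
#' @export
estimate_fdr <- function(x, labels, n_null = 500, confidence = 0.99,
                         fdr_threshold = 0.05, exact = FALSE, seed = NULL) {
  x <- as.matrix(x)
  if (ncol(x) < 1)
    plsvip_error("no features to rank", "plsvip_empty_table_error")
  labels <- as.character(labels)
  classes <- unique(labels)
  for (cl in classes)
    if (sum(labels == cl) < 4)
      plsvip_error(sprintf(
        "class '%s' has < 4 samples: cannot form two pseudo-groups", cl),
        "plsvip_null_infeasible_error")

  draw_nulls <- function() {
    nulls <- list()
    for (cl in classes) {
      rows <- which(labels == cl)
      n <- length(rows)
      h <- n %/% 2
      if (exact && n <= 12) {
        # fix rows[1] in the first pseudo-group to halve the enumeration
        combos <- utils::combn(n - 1, h - 1)
        for (ci in seq_len(ncol(combos))) {
          grp <- rep("b", n); grp[c(1, combos[, ci] + 1)] <- "a"
          nulls[[length(nulls) + 1]] <-
            anova_f_matrix(x[rows, , drop = FALSE], grp)
        }
      } else {
        for (d in seq_len(n_null)) {
          grp <- rep("b", n); grp[sample.int(n, h)] <- "a"
          nulls[[length(nulls) + 1]] <-
            anova_f_matrix(x[rows, , drop = FALSE], grp)
        }
      }
    }
    nulls
  }
  nulls <- if (is.null(seed)) draw_nulls() else with_seed(seed, draw_nulls())
  n_comparisons <- length(nulls)
  null_f <- unlist(nulls, use.names = FALSE)

  f_obs <- anova_f_matrix(x, labels)
  null_sorted <- sort(null_f[is.finite(null_f)])
  n_null_inf <- sum(is.infinite(null_f))
  null_exceed <- function(v) {
    # count of pooled null F values >= v
    if (is.infinite(v)) return(n_null_inf)
    length(null_sorted) - findInterval(v, null_sorted, left.open = TRUE) +
      n_null_inf
  }
  J <- ncol(x)
  ord <- order(f_obs, decreasing = TRUE)
  fdr <- numeric(J)
  for (r in seq_len(J)) {
    j <- ord[r]
    expected_false <- null_exceed(f_obs[j]) / n_comparisons
    fdr[j] <- min(1, expected_false / r)   # r = # observed F >= F_j
  }
  # step-up: enforce FDR non-increasing in F
  fdr[ord] <- cummax(fdr[ord])
  names(fdr) <- names(f_obs)

  structure(list(
    f = f_obs, fdr = fdr,
    panel = names(f_obs)[fdr <= fdr_threshold],
    fdr_threshold = fdr_threshold,
    null_f = null_f,
    null_threshold = stats::quantile(null_f, confidence, names = FALSE),
    confidence = confidence,
    n_comparisons = n_comparisons),
    class = "ftest_report")
}

#' @export
print.ftest_report <- function(x, ...) {
  cat(sprintf(
    "ftest_report: %d features, %d in panel (FDR <= %.2f)\n",
    length(x$f), length(x$panel), x$fdr_threshold))
  cat(sprintf("  null F threshold at %.0f%% confidence: %.3f (%d comparisons)\n",
              100 * x$confidence, x$null_threshold, x$n_comparisons))
  invisible(x)
}

#' PCA verification of class separation on a selected panel
#'
#' Autoscales the panel-restricted feature matrix and computes its
#' principal components, to visualize whether the selected features carry
#' the responder/non-responder separation.  As a scalar summary the mean
#' silhouette width of the class labels in PC1-PC2 space is reported (a
#' convenience metric of this implementation, not part of the classical
#' procedure; values near 1 mean clean separation, near 0 overlap).
#'
#' @param x feature matrix restricted to the panel (>= 2 features).
#' @param labels class labels for the rows.
#' @return List: `scores` (samples x PCs), `loadings`, `explained`
#'   (variance fractions, non-increasing), `silhouette` (mean width in
#'   PC1-PC2 space).
#' @export
pca_on_selected <- function(x, labels) {
  x <- as.matrix(x)
  if (ncol(x) < 2)
    plsvip_error("panel has fewer than 2 features: PCA infeasible",
                 "plsvip_infeasible_pca_error")
  sc <- autoscale(x)
  pr <- stats::prcomp(sc$x, center = FALSE, scale. = FALSE)
  explained <- pr$sdev^2 / sum(pr$sdev^2)
  k <- min(2, ncol(pr$x))
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             stats::dist(pr$x[, seq_len(k), drop = FALSE]))
  list(scores = pr$x, loadings = pr$rotation, explained = explained,
       silhouette = mean(sil[, "sil_width"]))
}
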