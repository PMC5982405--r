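#' Fit a PLS1 discriminant model by NIPALS
#'
#' Partial least squares regression of a single dummy-coded class variable
#' (+1 responder / -1 non-responder) on an autoscaled feature matrix, with
#' the classical NIPALS deflation.  For a univariate response the weight
#' vector of each component is obtained in closed form as the normalized
#' covariance `t(E) %*% f`, so no inner iteration is needed.
#'
#' @param x autoscaled numeric matrix (samples x features).
#' @param y numeric class codes (+1 / -1) or a factor/character label
#'   vector with levels responder / non-responder.
#' @param n_lv number of latent variables to extract; must satisfy
#'   `1 <= n_lv <= min(nrow(x) - 1, ncol(x))`.
#' @param partial if `TRUE`, stop early (returning the components extracted
#'   so far) when the X residual runs out of covariance with the response
#'   instead of raising a rank-exhausted error; used inside
#'   cross-validation folds.
#' @return An object of class `pls_model`: weights `W` (J x A, unit-norm
#'   columns), loadings `P` (J x A), y-loadings `q` (length A), regression
#'   vector `b` (length J), `y_mean`, per-component explained y-variance
#'   `ssy`, score sums of squares `tt`, and `n_lv`.  If the matrix passed
#'   in came from [autoscale()], attach its `center`/`scale` via
#'   [set_model_scaling()] before predicting raw-scale samples.
#' @references The NIPALS recurrence is the standard chemometrics PLS1
#'   algorithm (weights from the X-residual/y-residual covariance, score
#'   and loading deflation at each step).
#' @export
fit_pls <- function(x, y, n_lv, partial = FALSE) {
  x <- as.matrix(x)
  if (is.factor(y) || is.character(y)) y <- class_codes(y)
  y <- as.numeric(y)
  I <- nrow(x); J <- ncol(x)
  if (length(y) != I) plsvip_error("length(y) != nrow(x)", "plsvip_shape_error")
  if (n_lv < 1 || n_lv > min(I - 1, J))
    plsvip_error(sprintf("n_lv must be in [1, %d]", min(I - 1, J)),
                 "plsvip_config_error")
  y_mean <- mean(y)
  E <- x
  f <- y - y_mean
  W <- matrix(0, J, n_lv); P <- matrix(0, J, n_lv)
  q <- numeric(n_lv); tt <- numeric(n_lv)
  extracted <- 0L
  for (a in seq_len(n_lv)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      # residual X carries no covariance with the response
      if (partial && extracted >= 1L) break
      plsvip_error(sprintf(
        "rank exhausted at component %d: response orthogonal to X residual", a),
        "plsvip_rank_exhausted_error")
    }
    w <- w / nw
    t_a <- E %*% w
    tt[a] <- sum(t_a^2)
    p <- crossprod(E, t_a) / tt[a]
    q[a] <- sum(t_a * f) / tt[a]
    E <- E - tcrossprod(t_a, p)
    f <- f - q[a] * t_a
    W[, a] <- w; P[, a] <- p
    extracted <- a
  }
  if (extracted < n_lv) {
    W <- W[, seq_len(extracted), drop = FALSE]
    P <- P[, seq_len(extracted), drop = FALSE]
    q <- q[seq_len(extracted)]; tt <- tt[seq_len(extracted)]
    n_lv <- extracted
  }
  b <- .pls_coef(W, P, q, n_lv)
  structure(list(W = W, P = P, q = q, b = b, y_mean = y_mean,
                 ssy = q^2 * tt, tt = tt, n_lv = n_lv,
                 features = colnames(x), center = NULL, scale = NULL),
            class = "pls_model")
}

# Regression vector using the first `a` components: b = W (P'W)^{-1} q.
.pls_coef <- function(W, P, q, a) {
  Wa <- W[, seq_len(a), drop = FALSE]
  Pa <- P[, seq_len(a), drop = FALSE]
  drop(Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)]))
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d latent variable(s), %d features\n",
              x$n_lv, nrow(x$W)))
  invisible(x)
}

#' Attach calibration scaling parameters to a fitted model
#' @param model a `pls_model`.
#' @param center,scale parameters from [autoscale()] on the calibration set.
#' @return The model, with scaling applied automatically by [predict.pls_model()].
#' @export
set_model_scaling <- function(model, center, scale) {
  model$center <- center; model$scale <- scale
  model
}

#' Predict class codes for new samples
#' @param object a `pls_model`.
#' @param newdata numeric matrix with the model's feature columns; scaled
#'   with the stored calibration parameters if the model carries them,
#'   otherwise assumed already autoscaled.
#' @param ... unused.
#' @return Numeric vector of predicted class codes (continuous).
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$W))
    plsvip_error(sprintf("model has %d features but newdata has %d columns",
                         nrow(object$W), ncol(newdata)),
                 "plsvip_shape_error")
  if (!is.null(object$center))
    newdata <- apply_scaling(newdata, object$center, object$scale)
  drop(newdata %*% object$b) + object$y_mean
}

#' Hard classification and misclassification count
#'
#' Predicted class is responder iff the predicted code is at or above the
#' midpoint of the two class codes (0 for +1/-1 coding; exact ties go to
#' responder).
#'
#' @param model a `pls_model`.
#' @param newdata feature matrix for the samples to classify (see
#'   [predict.pls_model()] for scaling).
#' @param labels optional true labels (factor/character responder /
#'   non-responder, or +1/-1 codes) to score against.
#' @return List with `class` (factor), `yhat` (continuous predictions), and
#'   `misclassified` (count of disagreements; `NA` without labels).
#' @export
classify_samples <- function(model, newdata, labels = NULL) {
  yhat <- predict(model, newdata)
  cls <- factor(ifelse(yhat >= 0, RESPONDER, NON_RESPONDER),
                levels = c(NON_RESPONDER, RESPONDER))
  mis <- NA_integer_
  if (!is.null(labels)) {
    if (is.numeric(labels))
      labels <- ifelse(labels >= 0, RESPONDER, NON_RESPONDER)
    mis <- sum(as.character(cls) != as.character(labels))
  }
  list(class = cls, yhat = yhat, misclassified = mis)
}

#' Venetian-blind fold assignment
#'
#' Interleaved folds: the sample at position `i` goes to fold
#' `((i - 1) mod k) + 1`, the chemometrics "venetian blinds" scheme.
#'
#' @param I sample count.
#' @param k fold count, `2 <= k <= I`.
#' @return Integer vector of fold ids in `1..k`.
#' @export
venetian_blind_folds <- function(I, k) {
  if (k < 2) plsvip_error("k must be >= 2", "plsvip_config_error")
  if (I < k)
    plsvip_error(sprintf("cannot make %d folds from %d samples", k, I),
                 "plsvip_infeasible_fold_error")
  ((seq_len(I) - 1L) %% k) + 1L
}

# Order samples so the two classes alternate; combined with venetian-blind
# folds this puts both classes in every fold (the "simultaneous extraction
# of rows from both groups" arrangement).
interleave_classes <- function(y) {
  pos <- which(y > 0); neg <- which(y < 0)
  n <- max(length(pos), length(neg))
  ord <- as.vector(rbind(c(pos, rep(NA, n - length(pos))),
                         c(neg, rep(NA, n - length(neg)))))
  ord[!is.na(ord)]
}

#' RMSECV curve and latent-variable selection
#'
#' Venetian-blind k-fold cross-validation of the PLS1 class-code regression:
#' samples are first ordered class-interleaved so every fold mixes
#' responders and non-responders, then for each candidate component count
#' `a = 1..a_max` the left-out predictions are pooled into
#' `RMSECV(a) = sqrt(mean((yhat - y)^2))`.  Autoscaling parameters are
#' re-estimated on each fold's training portion (no leakage).  The chosen
#' latent-variable count minimizes RMSECV; ties go to the smaller count.
#'
#' @param x feature matrix on its raw (pre-autoscaling) scale.
#' @param y class codes or labels (see [fit_pls()]).
#' @param a_max largest component count to scan; capped at what the fold
#'   training sets can support.
#' @param k fold count (default 4).
#' @return An object of class `cv_curve`: `rmsecv` (named numeric, one per
#'   candidate), `n_lv` (the argmin), `a_max` (the cap actually used).
#' @export
rmsecv_curve <- function(x, y, a_max = NULL, k = 4) {
  x <- as.matrix(x)
  if (is.factor(y) || is.character(y)) y <- class_codes(y)
  I <- nrow(x); J <- ncol(x)
  a_max <- a_max %||% min(I - 2, 10)
  ord <- interleave_classes(y)
  x <- x[ord, , drop = FALSE]; y <- y[ord]
  folds <- venetian_blind_folds(I, k)
  a_cap <- min(a_max, J,
               min(vapply(seq_len(k), function(f) sum(folds != f),
                          numeric(1))) - 1)
  if (a_cap < 1)
    plsvip_error("too few samples for even one latent variable",
                 "plsvip_infeasible_fold_error")
  pred <- matrix(NA_real_, I, a_cap)
  a_eff <- a_cap
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    if (length(unique(sign(y[tr]))) < 2)
      plsvip_error(sprintf("fold %d training partition is single-class", f),
                   "plsvip_stratification_error")
    sc <- .scale_train(x[tr, , drop = FALSE])
    # partial fit: a fold whose X residual runs out of covariance with y
    # caps the scanned component range instead of aborting the curve
    fit <- fit_pls(sc$x, y[tr], n_lv = a_cap, partial = TRUE)
    a_eff <- min(a_eff, fit$n_lv)
    xte <- apply_scaling(x[te, , drop = FALSE], sc$center, sc$scale)
    for (a in seq_len(fit$n_lv)) {
      b_a <- .pls_coef(fit$W, fit$P, fit$q, a)
      pred[te, a] <- drop(xte %*% b_a) + fit$y_mean
    }
  }
  pred <- pred[, seq_len(a_eff), drop = FALSE]
  rmsecv <- sqrt(colMeans((pred - y)^2))
  names(rmsecv) <- paste0("LV", seq_len(a_eff))
  structure(list(rmsecv = rmsecv, n_lv = as.integer(which.min(rmsecv)),
                 a_max = a_eff),
            class = "cv_curve")
}

#' Variable Importance for Projection (VIP) scores
#'
#' For each feature j,
#' `VIP_j = sqrt( J * sum_a( SSY_a * w[j,a]^2 ) / sum_a(SSY_a) )`
#' where `SSY_a` is the response variance explained by component a and the
#' weight columns are unit-norm.  The scores satisfy `sum(VIP^2) = J`, so
#' VIP = 1 is the natural "average importance" reference point.
#'
#' @param model a fitted `pls_model`.
#' @return Named numeric vector of VIP scores, one per feature.
#' @export
vip_scores <- function(model) {
  ssy <- model$ssy
  total <- sum(ssy)
  if (total < 1e-300)
    plsvip_error("model explains no response variance: VIP undefined",
                 "plsvip_undefined_vip_error")
  J <- nrow(model$W)
  vip <- sqrt(J * drop(model$W^2 %*% ssy) / total)
  names(vip) <- model$features
  vip
}
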