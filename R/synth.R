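#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the statistical shape of an untargeted plasma lipidomics
#' study of antipsychotic response: roughly 1,600 LC-MS features, a 34:20
#' responder/non-responder split, log-normal abundances with multiplicative
#' per-sample total-ion-current (TIC) variation, a handful of
#' blank-contaminant and below-floor features, and a small planted subset of
#' class-discriminative lipids.
#'
#' @param n_responders,n_nonresponders sample counts per class.
#' @param n_features total number of m/z features (J).
#' @param n_informative number of features carrying a true class effect.
#' @param effect_size class mean shift on the log scale, in units of
#'   `noise_sd`.
#' @param log_mu_mean,log_mu_sd population of feature baseline
#'   log-abundances (natural log of arbitrary ion-count units).
#' @param noise_sd log-scale measurement noise standard deviation.
#' @param tic_sd log-scale spread of the per-sample TIC factor.
#' @param n_blank_features features that also appear in the blank injection
#'   (contaminants); their blank abundance matches their sample mean.
#' @param n_low_abundance features rescaled to sit below `abundance_floor`.
#' @param abundance_floor raw-scale floor used to plant low-abundance
#'   features (and the natural default for [filter_features()]'s
#'   `min_abundance`).
#' @param arm treatment arm label stamped on every sample.
#' @param seed integer seed; fully determines the generated dataset.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_responders = 34, n_nonresponders = 20,
                             n_features = 1600, n_informative = 20,
                             effect_size = 2, log_mu_mean = 12,
                             log_mu_sd = 1.5, noise_sd = 0.3, tic_sd = 0.2,
                             n_blank_features = 10, n_low_abundance = 10,
                             abundance_floor = 500, arm = "olanzapine",
                             seed = 1) {
  cfg <- list(n_responders = n_responders, n_nonresponders = n_nonresponders,
              n_features = n_features, n_informative = n_informative,
              effect_size = effect_size, log_mu_mean = log_mu_mean,
              log_mu_sd = log_mu_sd, noise_sd = noise_sd, tic_sd = tic_sd,
              n_blank_features = n_blank_features,
              n_low_abundance = n_low_abundance,
              abundance_floor = abundance_floor, arm = arm, seed = seed)
  counts <- c(n_responders, n_nonresponders, n_features, n_informative,
              n_blank_features, n_low_abundance)
  if (any(counts < 0) || effect_size < 0)
    plsvip_error("synthetic_config counts and effect_size must be >= 0",
                 "plsvip_config_error")
  if (n_responders == 0 || n_nonresponders == 0)
    plsvip_error("both classes need at least one sample",
                 "plsvip_config_error")
  if (n_informative > n_features)
    plsvip_error("n_informative exceeds n_features", "plsvip_config_error")
  if (n_informative + n_blank_features + n_low_abundance > n_features)
    plsvip_error("informative + blank + low-abundance exceeds n_features",
                 "plsvip_config_error")
  structure(cfg, class = "synthetic_config")
}

# Run expr under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic cohort dataset with planted ground truth
#'
#' Abundances follow a log-normal model:
#' `abundance[i, j] = exp(log_mu[j] + shift[i, j] + tic[i] + eps[i, j])`
#' with `log_mu[j] ~ N(log_mu_mean, log_mu_sd)`, a per-sample TIC factor
#' `tic[i] ~ N(0, tic_sd)`, measurement noise
#' `eps[i, j] ~ N(0, noise_sd)`, and a class shift of
#' `effect_size * noise_sd` applied on the log scale to responders on the
#' informative features only.  The sign of the shift alternates across
#' informative features so the signature is not one-sided.
#'
#' Blank-flagged features get a matched abundance in an emitted synthetic
#' blank sample (so the blank filter can find them); low-abundance features
#' are rescaled so their maximum sits below `abundance_floor`.  PANSS and
#' BMI metadata are drawn so that [classify_response()] reproduces the
#' planted class labels exactly.
#'
#' @param cfg a [synthetic_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{dataset}{a [cohort_dataset()] (the ground truth about which
#'       features are informative is *not* stored in it);}
#'     \item{truth}{list of `informative_features`, `effect_sign`,
#'       `blank_features`, `low_abundance_features` (feature ids);}
#'     \item{blank}{named numeric vector of blank-injection abundances,
#'       one per feature, for use as [filter_features()]'s `blank`.}
#'   }
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    I <- cfg$n_responders + cfg$n_nonresponders
    J <- cfg$n_features
    label <- rep(c(RESPONDER, NON_RESPONDER),
                 c(cfg$n_responders, cfg$n_nonresponders))
    feature_id <- sprintf("F%05d", seq_len(J))

    special <- sample.int(J, cfg$n_informative + cfg$n_blank_features +
                               cfg$n_low_abundance)
    informative <- special[seq_len(cfg$n_informative)]
    blank_idx <- special[cfg$n_informative + seq_len(cfg$n_blank_features)]
    low_idx <- special[cfg$n_informative + cfg$n_blank_features +
                         seq_len(cfg$n_low_abundance)]
    eff_sign <- rep_len(c(1, -1), cfg$n_informative)

    log_mu <- stats::rnorm(J, cfg$log_mu_mean, cfg$log_mu_sd)
    tic <- stats::rnorm(I, 0, cfg$tic_sd)
    eps <- matrix(stats::rnorm(I * J, 0, cfg$noise_sd), I, J)
    loga <- matrix(log_mu, I, J, byrow = TRUE) + tic + eps
    if (cfg$n_informative > 0) {
      shift <- cfg$effect_size * cfg$noise_sd
      is_resp <- label == RESPONDER
      for (k in seq_along(informative))
        loga[is_resp, informative[k]] <-
          loga[is_resp, informative[k]] + eff_sign[k] * shift
    }
    abundance <- exp(loga)
    # plant below-floor features: rescale so the column max is half the floor
    for (j in low_idx)
      abundance[, j] <- abundance[, j] *
        (cfg$abundance_floor / 2) / max(abundance[, j])

    blank <- stats::setNames(numeric(J), feature_id)
    blank[blank_idx] <- colMeans(abundance[, blank_idx, drop = FALSE])

    features <- data.frame(
      feature_id = feature_id,
      mz = round(sort(stats::runif(J, 100, 2000)), 4),
      rt = round(stats::runif(J, 0.5, 18), 3),
      stringsAsFactors = FALSE)

    samples <- .synth_metadata(I, label, cfg$arm)
    ds <- cohort_dataset(abundance, samples, features,
                         label = label)
    list(dataset = ds,
         truth = list(informative_features = feature_id[informative],
                      effect_sign = stats::setNames(eff_sign,
                                                    feature_id[informative]),
                      blank_features = feature_id[blank_idx],
                      low_abundance_features = feature_id[low_idx]),
         blank = blank)
  })
}

# Clinical metadata consistent with the planted labels: week-6 corrected
# PANSS totals are placed on the correct side of the 50%-reduction boundary.
.synth_metadata <- function(I, label, arm) {
  pos0 <- sample(15:32, I, replace = TRUE)
  neg0 <- sample(8:28, I, replace = TRUE)
  gen0 <- sample(20:45, I, replace = TRUE)
  corr0 <- (pos0 - 7) + (neg0 - 7) + (gen0 - 16)
  is_resp <- label == RESPONDER
  # responders: corrected total at week 6 <= 50% of baseline; others above
  frac <- ifelse(is_resp, stats::runif(I, 0.05, 0.50),
                 stats::runif(I, 0.55, 1.00))
  corr6 <- pmin(floor(corr0 * frac), ifelse(is_resp, floor(corr0 * 0.5),
                                            corr0))
  corr6 <- pmax(corr6, ifelse(is_resp, 0, floor(corr0 * 0.5) + 1))
  # split the week-6 corrected total across the three subscales
  split6 <- t(vapply(corr6,
                     function(tot) as.vector(stats::rmultinom(1, tot,
                                                              c(1, 1, 1))),
                     numeric(3)))
  bmi0 <- round(stats::rnorm(I, 24.5, 3), 1)
  bmi6 <- round(bmi0 + stats::rnorm(I, ifelse(is_resp, 1.2, 0.2), 1.4), 1)
  data.frame(
    sample_id = sprintf("S%03d", seq_len(I)),
    arm = arm,
    panss_pos_t0 = pos0, panss_neg_t0 = neg0, panss_gen_t0 = gen0,
    panss_pos_t6 = split6[, 1] + 7L,
    panss_neg_t6 = split6[, 2] + 7L,
    panss_gen_t6 = split6[, 3] + 16L,
    bmi_t0 = bmi0, bmi_t6 = bmi6,
    stringsAsFactors = FALSE)
}
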