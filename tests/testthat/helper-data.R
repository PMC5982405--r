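# Small dataset builders shared across test files.

make_cohort <- function(abundance, responder, mz = NULL, rt = NULL) {
  I <- nrow(abundance); J <- ncol(abundance)
  samples <- data.frame(sample_id = sprintf("S%02d", seq_len(I)),
                        arm = "olanzapine", stringsAsFactors = FALSE)
  features <- data.frame(feature_id = sprintf("F%03d", seq_len(J)),
                         mz = mz %||% seq(100, 900, length.out = J),
                         rt = rt %||% seq(1, 15, length.out = J),
                         stringsAsFactors = FALSE)
  cohort_dataset(abundance, samples, features,
                 label = ifelse(responder, "responder", "non-responder"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A clearly separable two-class matrix: planted columns shifted by `effect`
# standard units for the first class.
make_separable <- function(n1 = 10, n2 = 10, J = 30, planted = 3,
                           effect = 4, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm((n1 + n2) * J), n1 + n2, J)
  x[seq_len(n1), seq_len(planted)] <- x[seq_len(n1), seq_len(planted)] + effect
  colnames(x) <- sprintf("F%03d", seq_len(J))
  list(x = x, y = c(rep(1, n1), rep(-1, n2)))
}

# Benchmark dataset used by several tests: planted strong features in an
# otherwise null log-normal cohort (no blank/low-abundance features).
recovery_dataset <- function(seed = 101, effect_size = 5, n_features = 500,
                             n_informative = 10) {
  gen <- generate_dataset(synthetic_config(
    n_responders = 20, n_nonresponders = 20, n_features = n_features,
    n_informative = n_informative, effect_size = effect_size,
    n_blank_features = 0, n_low_abundance = 0, seed = seed))
  gen$dataset <- normalize_abundance(gen$dataset, "tic")
  gen
}
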