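# PANSS subscale minima: a score at the minimum represents absence of symptoms.
PANSS_FLOOR <- c(pos = 7L, neg = 7L, gen = 16L)

RESPONDER <- "responder"
NON_RESPONDER <- "non-responder"

#' Construct a cohort dataset
#'
#' Bundles a samples x features abundance matrix with per-sample clinical
#' metadata, per-feature descriptors, and a binary response label.  This is
#' the container every downstream stage (normalization, CV2 selection, F-test
#' ranking) operates on.
#'
#' @param abundance numeric matrix, samples in rows, features in columns;
#'   all values must be non-negative.
#' @param samples data frame with one row per sample.  Must contain
#'   `sample_id` and `arm`; PANSS columns (`panss_pos_t0`, `panss_neg_t0`,
#'   `panss_gen_t0` and the `_t6` counterparts) and `bmi_t0`/`bmi_t6` are
#'   optional but needed if the label has to be derived from the clinic
#'   scores.
#' @param features data frame with one row per feature: `feature_id`
#'   (unique), `mz` (> 0), `rt` (>= 0), optional `adduct` and `annotation`.
#' @param label character/factor of length `nrow(abundance)` with values
#'   `"responder"` / `"non-responder"`, or `NULL` to derive it from the
#'   PANSS columns via [classify_response()].
#'
#' @return An object of class `cohort_dataset`: a list with elements
#'   `abundance`, `samples`, `features`, `label` (factor with levels
#'   non-responder, responder).
#' @seealso [read_cohort()], [validate_dataset()]
#' @export
cohort_dataset <- function(abundance, samples, features, label = NULL) {
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  if (nrow(abundance) != nrow(samples))
    plsvip_error(sprintf(
      "abundance has %d rows but metadata has %d samples",
      nrow(abundance), nrow(samples)), "plsvip_shape_error")
  if (ncol(abundance) != nrow(features))
    plsvip_error(sprintf(
      "abundance has %d columns but %d feature descriptors were given",
      ncol(abundance), nrow(features)), "plsvip_shape_error")
  rownames(abundance) <- samples$sample_id
  colnames(abundance) <- features$feature_id
  if (is.null(label)) {
    label <- ifelse(
      classify_response(samples$panss_pos_t0, samples$panss_neg_t0,
                        samples$panss_gen_t0, samples$panss_pos_t6,
                        samples$panss_neg_t6, samples$panss_gen_t6),
      RESPONDER, NON_RESPONDER)
  }
  label <- factor(as.character(label), levels = c(NON_RESPONDER, RESPONDER))
  if (anyNA(label))
    plsvip_error("unresolvable response label for one or more samples",
                 "plsvip_label_error")
  structure(
    list(abundance = abundance, samples = samples,
         features = features, label = label),
    class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("cohort_dataset: %d samples x %d features\n",
              nrow(x$abundance), ncol(x$abundance)))
  cat(sprintf("  responders: %d, non-responders: %d\n",
              sum(x$label == RESPONDER), sum(x$label == NON_RESPONDER)))
  cat(sprintf("  arms: %s\n",
              paste(unique(as.character(x$samples$arm)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.cohort_dataset <- function(x) dim(x$abundance)

#' Classify treatment response from PANSS scores
#'
#' A favorable response is a reduction of at least 50% in the floor-corrected
#' total PANSS after six weeks of treatment.  Each subscale is corrected by
#' subtracting its scale minimum (7 positive, 7 negative, 16 general, the
#' scores that represent no symptoms) before the subscales are summed, so
#' that a symptom-free patient has a corrected total of zero.
#'
#' @param pos_t0,neg_t0,gen_t0 baseline PANSS positive/negative/general
#'   subscale scores.
#' @param pos_t6,neg_t6,gen_t6 the same subscales after six weeks.
#'
#' @return Logical vector: `TRUE` for responders.  A reduction of exactly
#'   50% counts as a response.
#' @details Vectorized over all six arguments.  Errors if any week-6 score
#'   is missing (the label is then unresolvable), if any score is below its
#'   subscale minimum, or if the corrected baseline total is zero (the
#'   relative reduction is then undefined).
#' @examples
#' classify_response(27, 17, 36, 12, 10, 21)  # 74% reduction -> TRUE
#' classify_response(20, 15, 30, 20, 15, 30)  # no change      -> FALSE
#' @export
classify_response <- function(pos_t0, neg_t0, gen_t0,
                              pos_t6, neg_t6, gen_t6) {
  scores <- cbind(pos_t0, neg_t0, gen_t0, pos_t6, neg_t6, gen_t6)
  if (anyNA(scores[, 4:6, drop = FALSE]))
    plsvip_error("week-6 PANSS scores missing: response label unresolvable",
                 "plsvip_label_error")
  if (anyNA(scores[, 1:3, drop = FALSE]))
    plsvip_error("baseline PANSS scores missing", "plsvip_label_error")
  floors <- PANSS_FLOOR[c("pos", "neg", "gen", "pos", "neg", "gen")]
  if (any(sweep(scores, 2, floors, `-`) < 0))
    plsvip_error("PANSS score below its subscale minimum (7/7/16)",
                 "plsvip_score_error")
  corr0 <- (pos_t0 - 7) + (neg_t0 - 7) + (gen_t0 - 16)
  corr6 <- (pos_t6 - 7) + (neg_t6 - 7) + (gen_t6 - 16)
  if (any(corr0 == 0))
    plsvip_error("corrected baseline PANSS total is zero: reduction undefined",
                 "plsvip_degenerate_baseline_error")
  corr6 <= 0.5 * corr0
}

.meta_columns <- c("feature_id", "mz", "rt", "adduct", "annotation")

#' Read a cohort dataset from a feature table and metadata file
#'
#' The feature table is delimited text (comma or tab, auto-detected from the
#' extension: `.tsv`/`.txt` means tab) with features as rows.  Its leading
#' columns are `feature_id`, `mz`, `rt` (optionally `adduct`, `annotation`)
#' followed by one abundance column per sample, headed by the sample ids.
#' The metadata file is a CSV with one row per sample (`sample_id`, `arm`,
#' PANSS and BMI columns, optionally `responder`).
#'
#' Metadata row order is canonical: abundance columns are permuted to match
#' it.  A sample present in only one of the two files is an alignment error;
#' a non-numeric abundance cell is a parse error reported with its
#' feature/sample coordinates (missing values are not imputed).
#'
#' @param table_path path to the feature table.
#' @param metadata_path path to the sample metadata CSV.
#' @return A [cohort_dataset()].
#' @export
read_cohort <- function(table_path, metadata_path) {
  sep <- if (grepl("\\.(tsv|txt)$", table_path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(table_path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  if (!"feature_id" %in% names(tab))
    plsvip_error("feature table lacks a feature_id column",
                 "plsvip_parse_error")
  sample_cols <- setdiff(names(tab), .meta_columns)
  missing_meta <- setdiff(sample_cols, meta$sample_id)
  if (length(missing_meta))
    plsvip_error(sprintf(
      "sample(s) in feature table but not in metadata: %s",
      paste(missing_meta, collapse = ", ")), "plsvip_alignment_error")
  missing_tab <- setdiff(meta$sample_id, sample_cols)
  if (length(missing_tab))
    plsvip_error(sprintf(
      "sample(s) in metadata but not in feature table: %s",
      paste(missing_tab, collapse = ", ")), "plsvip_alignment_error")

  ab_chr <- as.matrix(tab[, meta$sample_id, drop = FALSE])
  suppressWarnings(ab_num <- matrix(as.numeric(ab_chr), nrow = nrow(ab_chr),
                                    dimnames = dimnames(ab_chr)))
  bad <- which(is.na(ab_num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    plsvip_error(sprintf(
      "non-numeric abundance value '%s' at feature %s, sample %s",
      ab_chr[bad[1, 1], bad[1, 2]], tab$feature_id[bad[1, 1]],
      meta$sample_id[bad[1, 2]]), "plsvip_parse_error")
  }

  features <- data.frame(
    feature_id = tab$feature_id,
    mz = as.numeric(tab$mz %||% rep(NA_real_, nrow(tab))),
    rt = as.numeric(tab$rt %||% rep(NA_real_, nrow(tab))),
    stringsAsFactors = FALSE)
  if ("adduct" %in% names(tab)) features$adduct <- tab$adduct
  if ("annotation" %in% names(tab)) features$annotation <- tab$annotation

  label <- NULL
  if ("responder" %in% names(meta) && !anyNA(meta$responder)) {
    label <- ifelse(as.logical(meta$responder), RESPONDER, NON_RESPONDER)
  }
  cohort_dataset(t(ab_num), meta, features, label = label)
}

#' Write a cohort dataset to a feature table and metadata CSV
#'
#' Inverse of [read_cohort()]: features as rows with `feature_id`, `mz`,
#' `rt` leading columns, then one column per sample in metadata order.
#' Numbers are written with full precision so a read/write round trip
#' reproduces finite decimal inputs exactly.
#'
#' @param ds a [cohort_dataset()].
#' @param table_path,metadata_path output paths (CSV).
#' @return Invisibly, `ds`.
#' @export
write_cohort <- function(ds, table_path, metadata_path) {
  tab <- data.frame(feature_id = ds$features$feature_id,
                    mz = ds$features$mz, rt = ds$features$rt,
                    stringsAsFactors = FALSE)
  ab <- t(ds$abundance)
  for (i in seq_len(ncol(ab))) {
    tab[[rownames(ds$abundance)[i]]] <-
      vapply(ab[, i], function(v) format(v, digits = 17, scientific = FALSE,
                                         trim = TRUE), character(1))
  }
  utils::write.csv(tab, table_path, row.names = FALSE, quote = FALSE)
  meta <- ds$samples
  meta$responder <- ds$label == RESPONDER
  utils::write.csv(meta, metadata_path, row.names = FALSE, quote = FALSE)
  invisible(ds)
}

#' Validate a cohort dataset for modeling
#'
#' Checks the container invariants (non-negative abundances, unique feature
#' ids, positive m/z, non-negative retention times, matching dimensions) and
#' modeling readiness (both classes non-empty, at least two features).
#' Violations are reported, not thrown, so a caller can inspect all of them
#' at once.
#'
#' @param ds a [cohort_dataset()].
#' @return Data frame with columns `rule` and `detail`, one row per
#'   violation; zero rows iff the dataset is modeling-ready.
#' @export
validate_dataset <- function(ds) {
  bad <- list()
  note <- function(rule, detail)
    bad[[length(bad) + 1]] <<- data.frame(rule = rule, detail = detail,
                                          stringsAsFactors = FALSE)
  neg <- which(ds$abundance < 0, arr.ind = TRUE)
  for (k in seq_len(nrow(neg)))
    note("negative_abundance",
         sprintf("sample %s, feature %s",
                 rownames(ds$abundance)[neg[k, 1]],
                 colnames(ds$abundance)[neg[k, 2]]))
  dup <- ds$features$feature_id[duplicated(ds$features$feature_id)]
  for (d in unique(dup)) note("duplicate_feature_id", d)
  for (f in ds$features$feature_id[!is.na(ds$features$mz) & ds$features$mz <= 0])
    note("nonpositive_mz", f)
  for (f in ds$features$feature_id[!is.na(ds$features$rt) & ds$features$rt < 0])
    note("negative_rt", f)
  counts <- table(ds$label)
  if (any(counts == 0))
    note("single_class",
         sprintf("class '%s' has no samples", names(counts)[counts == 0][1]))
  if (ncol(ds$abundance) < 2)
    note("too_few_features", sprintf("J = %d < 2", ncol(ds$abundance)))
  if (length(bad) == 0)
    return(data.frame(rule = character(), detail = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, bad)
}

# Internal: +1 / -1 dummy coding of the response label.
class_codes <- function(label) ifelse(label == RESPONDER, 1, -1)

# Internal: subset a cohort to a feature id set, preserving order.
subset_features <- function(ds, feature_ids) {
  keep <- ds$features$feature_id %in% feature_ids
  ds$abundance <- ds$abundance[, keep, drop = FALSE]
  ds$features <- ds$features[keep, , drop = FALSE]
  ds
}
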