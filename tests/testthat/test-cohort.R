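test_that("responder classification applies the floor-corrected 50% rule", {
  # 74% reduction of the corrected total
  expect_true(classify_response(27, 17, 36, 12, 10, 21))
  # unchanged scores: 0% reduction
  expect_false(classify_response(20, 15, 30, 20, 15, 30))
  # reduction of exactly 50% counts as a response (inclusive boundary)
  expect_true(classify_response(27, 17, 36, 17, 12, 26))
  # just above the boundary is not a response
  expect_false(classify_response(27, 17, 36, 17, 12, 27))
})

test_that("responder classification is invariant to subscale ordering and
           handles symptom-free week 6", {
  set.seed(4)
  for (i in 1:20) {
    s0 <- c(sample(8:30, 2), sample(17:40, 1))
    s6 <- c(sample(8:30, 2), sample(17:40, 1))
    base <- classify_response(s0[1], s0[2], s0[3], s6[1], s6[2], s6[3])
    # swapping the two subscales that share the floor of 7 cannot matter
    expect_identical(
      classify_response(s0[2], s0[1], s0[3], s6[2], s6[1], s6[3]), base)
  }
  # corrected week-6 total of zero with positive baseline is always a response
  expect_true(classify_response(25, 20, 30, 7, 7, 16))
})

test_that("responder classification rejects unusable inputs", {
  expect_error(classify_response(27, 17, 36, NA, 10, 21),
               class = "plsvip_label_error")
  expect_error(classify_response(7, 7, 16, 8, 8, 17),
               class = "plsvip_degenerate_baseline_error")
  expect_error(classify_response(5, 17, 36, 12, 10, 21),
               class = "plsvip_score_error")
})

test_that("read_cohort aligns table columns to metadata order", {
  dir <- withr::local_tempdir()
  ab <- matrix(c(2, 3, 5, 7,
                 11, 13, 17, 19,
                 23, 29, 31, 37), nrow = 3, byrow = TRUE)
  tab <- data.frame(feature_id = c("F1", "F2", "F3"),
                    mz = c(120.5, 340.25, 560.125), rt = c(1.5, 5, 9.25))
  sample_ids <- c("S1", "S2", "S3", "S4")
  for (i in 1:4) tab[[sample_ids[i]]] <- ab[, i]
  tp <- file.path(dir, "tab.csv")
  write.csv(tab, tp, row.names = FALSE, quote = FALSE)
  meta <- data.frame(sample_id = c("S3", "S1", "S4", "S2"),
                     arm = "risperidone", responder = c(TRUE, TRUE, FALSE, FALSE))
  mp <- file.path(dir, "meta.csv")
  write.csv(meta, mp, row.names = FALSE, quote = FALSE)

  ds <- read_cohort(tp, mp)
  expect_equal(dim(ds), c(4L, 3L))
  # metadata order is canonical: abundance rows were permuted to match
  expect_identical(rownames(ds$abundance), c("S3", "S1", "S4", "S2"))
  expect_equal(unname(ds$abundance["S3", ]), ab[, 3])
  expect_equal(as.character(ds$label),
               c("responder", "responder", "non-responder", "non-responder"))
})

test_that("read_cohort reports alignment and parse failures by name", {
  dir <- withr::local_tempdir()
  tab <- data.frame(feature_id = "F1", mz = 100, rt = 2, S1 = 1, S9 = 2)
  tp <- file.path(dir, "tab.csv"); write.csv(tab, tp, row.names = FALSE)
  meta <- data.frame(sample_id = "S1", arm = "olanzapine", responder = TRUE)
  mp <- file.path(dir, "meta.csv"); write.csv(meta, mp, row.names = FALSE)
  expect_error(read_cohort(tp, mp), regexp = "S9",
               class = "plsvip_alignment_error")

  tab2 <- data.frame(feature_id = c("F1", "F2"), mz = c(100, 200),
                     rt = c(2, 3), S1 = c("1.5", "NA"), S2 = c("2", "3"))
  tp2 <- file.path(dir, "tab2.csv"); write.csv(tab2, tp2, row.names = FALSE)
  meta2 <- data.frame(sample_id = c("S1", "S2"), arm = "olanzapine",
                      responder = c(TRUE, FALSE))
  mp2 <- file.path(dir, "meta2.csv"); write.csv(meta2, mp2, row.names = FALSE)
  err <- expect_error(read_cohort(tp2, mp2), class = "plsvip_parse_error")
  expect_match(conditionMessage(err), "F2")
  expect_match(conditionMessage(err), "S1")
})

test_that("write_cohort / read_cohort round trip is exact for decimal data", {
  dir <- withr::local_tempdir()
  ab <- matrix(c(2.5, 3.125, 1019.75, 0.0625, 7, 42.5), nrow = 2,
               byrow = TRUE)
  ds <- make_cohort(ab, responder = c(TRUE, FALSE))
  write_cohort(ds, file.path(dir, "t.csv"), file.path(dir, "m.csv"))
  back <- read_cohort(file.path(dir, "t.csv"), file.path(dir, "m.csv"))
  expect_identical(back$abundance, ds$abundance)
  expect_identical(as.character(back$label), as.character(ds$label))
})

test_that("validate_dataset reports invariant violations without throwing", {
  ab <- matrix(c(1, 2, 3, 4), 2, 2)
  ds <- make_cohort(ab, responder = c(TRUE, FALSE))
  expect_equal(nrow(validate_dataset(ds)), 0)

  ds$abundance[2, 1] <- -1
  rep <- validate_dataset(ds)
  expect_equal(rep$rule, "negative_abundance")
  expect_match(rep$detail, "S02")
  expect_match(rep$detail, "F001")

  ds2 <- make_cohort(ab, responder = c(TRUE, TRUE))
  expect_true("single_class" %in% validate_dataset(ds2)$rule)
})
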