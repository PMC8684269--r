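test_that("long-stay labelling uses the 7-day threshold inclusively", {
  expect_equal(label_long_stay(c(7.0, 6.9, 2.1, 11)), c(1L, 0L, 0L, 1L))
  expect_equal(label_long_stay(6, srf_params(long_stay_threshold_days = 6)),
               1L)
  expect_error(label_long_stay(c(3, -1)), "positive")
})

test_that("srf score matches its closed form and the published cutoff", {
  expect_equal(round(srf_score(55, 45), 3), 1.688)
  expect_equal(srf_score(0, 0), 1)
  expect_equal(srf_score(100, 1), log2(102))
  expect_equal(srf_score(10, 40), srf_score(40, 10))
  expect_equal(srf_score(10, 40), log2(6))
  expect_error(srf_score(-1, 2), "non-negative")
  expect_error(srf_score(1.5, 2), "non-negative")
})

test_that("srf is symmetric, bounded below and monotone in the max count", {
  set.seed(7)
  a <- sample(0:200, 300, replace = TRUE)
  c <- sample(0:200, 300, replace = TRUE)
  expect_equal(srf_score(a, c), srf_score(c, a))
  expect_true(all(srf_score(a, c) >= 1))
  # non-decreasing in a for fixed c once a is the dominating count
  for (cc in c(0, 3, 17)) {
    s <- srf_score(cc:250, cc)
    expect_true(all(diff(s) >= 0))
  }
})

test_that("the derived cutoff excludes boundary and balanced concepts", {
  p <- srf_params()
  expect_equal(round(p$srf_cutoff, 3), 1.688)
  expect_gt(srf_cutoff(0.3), log2(3))
  expect_error(srf_params(prevalence_threshold = 0.6), "0, 0.5")
  inc <- data.frame(concept_id = c("x", "y", "z"),
                    a = c(55, 90, 50), c = c(45, 10, 50))
  expect_equal(filter_relevant_concepts(inc, p), "y")
  rep <- srf_report(inc, p)
  expect_equal(rep$kept, c(FALSE, TRUE, FALSE))
  expect_equal(filter_relevant_concepts(inc[0, ], p), character(0))
})

test_that("ICD-10 roll-up reproduces the documented example", {
  m <- rollup_icd10(c(M6289 = 3, M628 = 1, M62 = 0))
  expect_equal(unname(m[c("M6289", "M628", "M62")]),
               c("M62", "M62", "M62"))
  expect_equal(unname(rollup_icd10(c(J189 = 212))["J189"]), "J189")
  expect_equal(unname(rollup_icd10(c(A00 = 1))["A00"]), "A00")
  expect_error(rollup_icd10(c(M6 = 2)), "at least 3")
  # two rare siblings pool at their parent and both survive there
  m <- rollup_icd10(c(K351 = 3, K352 = 3))
  expect_equal(unname(m), c("K35", "K35"))
})

test_that("roll-up matches the brute-force fix point on random tables", {
  for (seed in 1:12) {
    counts <- random_code_counts(sample(5:30, 1), seed)
    m <- rollup_icd10(counts)
    expect_identical(m[names(counts)], brute_rollup(counts)[names(counts)],
                     label = paste("seed", seed))
    pooled <- tapply(as.numeric(counts), m[names(counts)], sum)
    expect_true(all(pooled >= 5 | nchar(names(pooled)) == 3))
  }
})

test_that("CCMU letters map to the ends of the numeric scale", {
  expect_equal(encode_ccmu(c("D", "P", "3", "1", "5")), c(6L, 0L, 3L, 1L, 5L))
  expect_error(encode_ccmu("Q"), "illegal CCMU")
})

test_that("recent-visit flag uses a half-open 7-day window", {
  t0 <- as.POSIXct("2019-03-10 12:00:00", tz = "UTC")
  expect_equal(recent_visit_flag(t0, t0 - 3 * 86400), 1L)
  expect_equal(recent_visit_flag(t0, character(0)), 0L)
  expect_equal(recent_visit_flag(t0, t0 - 8 * 86400), 0L)
  expect_equal(recent_visit_flag(t0, t0 - 7 * 86400), 1L)  # boundary in
  expect_error(recent_visit_flag(t0, t0 + 86400), "after the index")
})

test_that("prior-admission counts match a naive double loop", {
  set.seed(11)
  tt <- as.POSIXct("2019-01-01", tz = "UTC") + runif(80, 0, 40 * 86400)
  k <- prior_admission_counts(tt)
  naive <- vapply(seq_along(tt), function(i)
    sum(tt >= tt[i] - 7 * 86400 & tt < tt[i]), 0L)
  expect_equal(k, naive)
})

test_that("activity index interpolates between the outer deciles", {
  # craft counts directly: deciles of 0:10 replicated are d1=1, d9=9
  k <- rep(0:10, each = 10)
  idx <- activity_index(NULL, counts = k)
  d <- quantile(k, c(0.1, 0.9), names = FALSE)
  expect_equal(idx[k < d[1]], rep(0, sum(k < d[1])))
  expect_equal(idx[k > d[2]], rep(1, sum(k > d[2])))
  mid <- which(k == round((d[1] + d[2]) / 2))
  expect_equal(idx[mid], rep(0.5, length(mid)))
  expect_true(all(idx >= 0 & idx <= 1))
  expect_true(all(diff(idx[order(k)]) >= 0))
  expect_warning(const <- activity_index(NULL, counts = rep(4, 30)),
                 "degenerate")
  expect_equal(const, rep(0.5, 30))
})

test_that("feature sets contain exactly their specified blocks", {
  fx <- demo_cohort()
  sets <- extract_stay_concepts(fx$notes, fx$th, default_cues("en"))
  train <- fx$stays$stay_id[1:200]
  fm_c <- build_feature_matrix(fx$stays, NULL, "common", train)
  fm_s <- build_feature_matrix(fx$stays, NULL, "structured", train)
  fm_u <- build_feature_matrix(fx$stays, sets, "unstructured", train)

  expect_false(any(grepl("^(icd_|gemsa_|concept_|ccmu)",
                         colnames(fm_c$x))))
  expect_true(any(grepl("^icd_", colnames(fm_s$x))))
  expect_true("ccmu" %in% colnames(fm_s$x))
  expect_true(any(grepl("^concept_", colnames(fm_u$x))))
  expect_false(any(grepl("^(icd_|gemsa_|ccmu)", colnames(fm_u$x))))

  # common columns identical row for row across the three sets
  common_cols <- colnames(fm_c$x)
  expect_identical(fm_s$x[, common_cols], fm_c$x)
  expect_identical(fm_u$x[, common_cols], fm_c$x)

  # one-hot blocks are binary; ICD block has exactly one 1 per training row
  tr <- fm_s$stay_ids %in% train
  icd_block <- fm_s$x[, grepl("^icd_", colnames(fm_s$x)), drop = FALSE]
  expect_true(all(icd_block %in% c(0, 1)))
  expect_true(all(rowSums(icd_block[tr, , drop = FALSE]) == 1))
  # concept block can carry several 1s per row
  cb <- fm_u$x[, grepl("^concept_", colnames(fm_u$x)), drop = FALSE]
  expect_true(all(cb %in% c(0, 1)))
  expect_gt(max(rowSums(cb)), 1)
  # activity index stays in [0,1]
  expect_true(all(fm_c$x[, "activity_index"] >= 0 &
                    fm_c$x[, "activity_index"] <= 1))
})

test_that("unseen categories map to all-zero one-hot rows", {
  fx <- demo_cohort()
  stays <- fx$stays
  stays$ward[250] <- "brand_new_ward"
  stays$icd10[250] <- "Z9999"
  fm <- build_feature_matrix(stays, NULL, "structured",
                             train_ids = stays$stay_id[1:200])
  ward_block <- fm$x[250, grepl("^ward_", colnames(fm$x))]
  expect_equal(sum(ward_block), 0)
})

test_that("feature matrices never leak test-set outcomes", {
  fx <- demo_cohort()
  sets <- extract_stay_concepts(fx$notes, fx$th, default_cues("en"))
  train <- fx$stays$stay_id[1:200]
  base <- build_feature_matrix(fx$stays, sets, "unstructured", train)
  shuffled <- fx$stays
  test_rows <- !(shuffled$stay_id %in% train)
  set.seed(3)
  shuffled$total_los[test_rows] <- sample(shuffled$total_los[test_rows])
  again <- build_feature_matrix(shuffled, sets, "unstructured", train)
  expect_identical(again$x, base$x)
  expect_identical(again$encoder$relevant_concepts,
                   base$encoder$relevant_concepts)
})
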