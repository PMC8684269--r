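test_that("train/test split is disjoint, exhaustive and deterministic", {
  ids <- sprintf("s%02d", 1:10)
  sp <- split_train_test(ids, 0.8, seed = 4)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(split_train_test(ids, 0.8, seed = 4), sp)
  expect_false(identical(split_train_test(ids, 0.8, seed = 5), sp))
  # round-half-even at the study size
  big <- split_train_test(as.character(1:5006), 0.8, seed = 1)
  expect_length(big$train, 4005)
  expect_length(big$test, 1001)
  expect_error(split_train_test(ids, 1.2, seed = 1), "in \\(0, 1\\)")
  expect_error(split_train_test(ids[1:5], 0.8, seed = 1), "at least 10")
})

test_that("search space enforces its documented bounds", {
  expect_error(search_space(min_samples_split = c(2, 50)), "at least 5")
  expect_error(search_space(n_folds = 1), "at least 2")
  expect_error(search_space(n_estimators = c(100, 50)), "increasing")
  sp <- search_space()
  expect_equal(sp$n_iterations, 50L)
  expect_equal(sp$n_folds, 3L)
})

make_toy_matrix <- function(n = 240, p = 6, seed = 8) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", 1:p)))
  y <- as.integer(x[, 1] + 0.5 * x[, 2] + rnorm(n, 0, 0.5) > 0)
  list(x = x, y = y)
}

test_that("random search samples the space and degenerates correctly", {
  d <- make_toy_matrix()
  one <- search_space(n_iterations = 1, n_folds = 3)
  r1 <- random_search_cv(d$x, d$y, one, seed = 2)
  expect_equal(nrow(r1$results), 1)
  expect_identical(r1$best_params, as.list(r1$results[1, 1:3]))

  point <- search_space(n_estimators = c(80, 80),
                        min_samples_split = c(5, 5),
                        min_samples_leaf = c(2, 2),
                        n_iterations = 3, n_folds = 3)
  rp <- random_search_cv(d$x, d$y, point, seed = 2)
  expect_equal(rp$best_params,
               list(n_estimators = 80L, min_samples_split = 5L,
                    min_samples_leaf = 2L))
  # with a collapsed space every candidate scores the same plain CV accuracy
  expect_true(all(abs(rp$results$cv_accuracy - rp$best_score) < 1e-12))

  sp <- search_space(n_iterations = 4, n_folds = 3)
  expect_identical(random_search_cv(d$x, d$y, sp, seed = 7),
                   random_search_cv(d$x, d$y, sp, seed = 7))
  # one-class fold is refused with guidance
  y_bad <- rep(0L, nrow(d$x))
  expect_error(random_search_cv(d$x, y_bad, sp, seed = 1), "one-class")
})

test_that("forest fits are deterministic, separable when trivially so", {
  set.seed(21)
  y <- rep(0:1, each = 40)
  x <- cbind(signal = y, noise = rnorm(80))
  params <- list(n_estimators = 60, min_samples_split = 5,
                 min_samples_leaf = 1)
  fit <- fit_forest(x, y, params, seed = 3)
  expect_equal(predict(fit, x), y)
  imp <- importance_scores(fit)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_equal(imp$feature[1], "signal")
  fit2 <- fit_forest(x, y, params, seed = 3)
  expect_identical(predict(fit2, x), predict(fit, x))
  expect_error(fit_forest(x[0, ], integer(0), params), "empty")
})

test_that("random labels give chance-level held-out accuracy", {
  set.seed(33)
  x <- matrix(rnorm(300 * 5), 300, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- rbinom(300, 1, 0.5)
  fit <- fit_forest(x[1:200, ], y[1:200],
                    list(n_estimators = 100, min_samples_split = 5,
                         min_samples_leaf = 2), seed = 1)
  acc <- mean(predict(fit, x[201:300, ]) == y[201:300])
  maj <- max(mean(y[201:300]), 1 - mean(y[201:300]))
  expect_lt(acc, maj + 3 * sqrt(0.25 / 100))
})

test_that("metric identities hold on a hand-computed confusion matrix", {
  # tp=3 tn=2 fp=1 fn=2
  pred <- c(1, 1, 1, 1, 0, 0, 0, 0)
  lab <- c(1, 1, 1, 0, 1, 1, 0, 0)
  m <- evaluate(pred, lab)
  expect_equal(c(m$tp, m$tn, m$fp, m$fn), c(3, 2, 1, 2))
  expect_equal(m$accuracy, 0.625)
  expect_equal(m$recall, 0.6)
  expect_equal(m$specificity, 2 / 3)
  expect_equal(m$precision, 0.75)
  expect_equal(m$f1, 2 / 3)

  perfect <- evaluate(lab, lab)
  expect_equal(unlist(perfect[c("recall", "specificity", "precision",
                                "accuracy", "f1")]),
               c(recall = 1, specificity = 1, precision = 1, accuracy = 1,
                 f1 = 1))
  allpos <- evaluate(rep(1, 8), lab)
  expect_equal(allpos$specificity, 0)
  expect_error(evaluate(pred, lab[1:3]), "length")
})

test_that("concordance counts identical predictions", {
  a <- c(1, 0, 1, 1, 0)
  expect_equal(concordance(a, a)$fraction, 1)
  expect_equal(concordance(a, 1 - a)$fraction, 0)
  set.seed(2)
  b <- rbinom(50, 1, 0.5)
  b2 <- b; b2[1:7] <- 1 - b2[1:7]
  cc <- concordance(b, b2)
  expect_equal(cc$fraction, 0.86)
  expect_equal(sum(cc$table), 50)
  expect_error(concordance(a, a[1:2]), "length")
})

comparison_to_list_safe <- function(x) edlos:::comparison_to_list(x)

test_that("comparison is deterministic and immune to test-label changes", {
  fx <- demo_cohort()
  sets <- cached("demo_sets", function()
    extract_stay_concepts(fx$notes, fx$th, default_cues("en")))
  cfg <- comparison_config(seed = 5,
                           space = search_space(n_iterations = 2,
                                                n_estimators = c(40, 80)))
  res1 <- run_comparison(fx$stays, sets, cfg)
  res2 <- run_comparison(fx$stays, sets, cfg)
  expect_identical(comparison_to_list_safe(res1),
                   comparison_to_list_safe(res2))
  expect_true(res1$concordance$fraction >=
                res1$structured$metrics$accuracy +
                res1$unstructured$metrics$accuracy - 1)

  # perturbing only test-set outcomes leaves the fitted models unchanged
  perturbed <- fx$stays
  test_rows <- perturbed$stay_id %in% res1$test_ids
  perturbed$total_los[test_rows] <-
    pmax(perturbed$total_los[test_rows] + 5, 7.5)
  res3 <- run_comparison(perturbed, sets, cfg)
  expect_identical(res3$predictions, res1$predictions)
})
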