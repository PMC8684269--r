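test_that("generator configuration is validated", {
  expect_error(generator_config(n_concepts = 2), "at least 3")
  expect_error(generator_config(ubiquitous_concept_prevalence = 1.2),
               "outside")
  expect_error(generator_config(n_concepts = 10,
                                n_informative_concepts = 11),
               "must not exceed")
  expect_error(generator_config(study_start = "2019-06-01",
                                study_end = "2019-01-01"), "empty")
})

test_that("generated thesaurus is a rooted hierarchy with shared substrings", {
  cfg <- generator_config(n_concepts = 50, seed = 1)
  th <- generate_thesaurus(cfg)
  expect_equal(nrow(th$concepts), 50)
  roots <- th$concepts$concept_id[is.na(th$concepts$parent_id)]
  expect_length(roots, 1)
  # every non-root has exactly one parent, chain ends at the root
  for (id in setdiff(th$concepts$concept_id, roots)) {
    anc <- concept_ancestors(th, id)
    expect_equal(anc[length(anc)], roots)
  }
  # at least two levels and a parent-child term substring pair
  lv <- attr(th, "level")
  expect_gte(max(lv), 2)
  kids <- th$concepts[!is.na(th$concepts$parent_id), ]
  pair <- mapply(function(kid, par) {
    pt <- th$concepts$preferred_term[th$concepts$concept_id == par]
    grepl(pt, kid, fixed = TRUE)
  }, kids$preferred_term, kids$parent_id)
  expect_true(any(pair))
  # minimal configuration still yields a 2-level tree with terms everywhere
  th3 <- generate_thesaurus(generator_config(n_concepts = 3, seed = 2))
  expect_equal(nrow(th3$concepts), 3)
  expect_true(all(nzchar(th3$concepts$preferred_term)))
  expect_gte(max(attr(th3, "level")), 1)
})

test_that("generation is deterministic under the seed", {
  cfg <- generator_config(n_stays = 40, seed = 9, n_concepts = 20)
  expect_identical(generate_thesaurus(cfg), generate_thesaurus(cfg))
  th <- generate_thesaurus(cfg)
  expect_identical(generate_cohort(cfg, th), generate_cohort(cfg, th))
  # a different seed changes the draw
  cfg2 <- generator_config(n_stays = 40, seed = 10, n_concepts = 20)
  expect_false(identical(generate_cohort(cfg2, generate_thesaurus(cfg2)),
                         generate_cohort(cfg, th)))
})

test_that("cohort honours the inclusion rule and emulated prevalences", {
  fx <- demo_cohort()
  s <- fx$stays
  expect_equal(nrow(s), fx$cfg$n_stays)
  # inclusion: more than two days in the post-ED ward; LOS includes ED time
  expect_true(all(s$total_los - s$ed_los / 24 > 2))
  expect_true(all(s$ed_exit_time > s$ed_entry_time))
  expect_equal(as.numeric(difftime(s$ed_exit_time, s$ed_entry_time,
                                   units = "hours")),
               s$ed_los, tolerance = 1e-6)
  # long-tailed LOS around the documented median
  expect_gt(median(s$total_los), 5)
  expect_lt(median(s$total_los), 8.5)
  # near-ubiquitous concept plants at its configured prevalence
  ubiq <- attr(fx$th, "ubiquitous_id")
  gt <- gt_affirmed(fx$notes)
  phat <- mean(vapply(gt, function(g) ubiq %in% g, TRUE))
  expect_gt(phat, 0.95)
  # recent-visit flag non-degenerate near its 13% design rate
  flags <- edlos:::recent_visit_flags(s)
  expect_gt(mean(flags), 0.08)
  expect_lt(mean(flags), 0.18)
  # planted affirmation mentions per note near the configured mean
  per_note <- vapply(fx$notes, function(n)
    sum(n$ground_truth$subject == "patient" &
          n$ground_truth$polarity == "affirmation"), 0)
  expect_lt(abs(mean(per_note) - fx$cfg$mean_concepts_per_note), 2.5)
  # negated and family sentences present and recorded
  pol <- unlist(lapply(fx$notes, function(n) n$ground_truth$polarity))
  subj <- unlist(lapply(fx$notes, function(n) n$ground_truth$subject))
  expect_gt(sum(pol == "negation"), 0)
  expect_gt(sum(subj == "family"), 0)
})

test_that("every planted mention is recoverable by substring search", {
  fx <- demo_cohort()
  for (note in fx$notes[1:30]) {
    norm_sents <- normalize_term(note$sentences)
    for (cid in note$ground_truth$concept_id) {
      row <- fx$th$concepts[fx$th$concepts$concept_id == cid, ]
      terms <- normalize_term(c(row$preferred_term,
                                strsplit(row$synonyms, "|",
                                         fixed = TRUE)[[1]]))
      found <- any(vapply(terms, function(tm)
        any(grepl(tm, norm_sents, fixed = TRUE)), TRUE))
      expect_true(found, label = paste("concept", cid, "in note",
                                       note$stay_id))
    }
  }
})

test_that("cohort artifacts round-trip through CSV and JSON-lines", {
  fx <- demo_cohort()
  dir <- withr::local_tempdir()
  paths <- write_cohort(list(stays = fx$stays, notes = fx$notes[1:15]),
                        fx$th, dir)
  s2 <- read_stays(paths[["stays"]])
  expect_equal(s2$stay_id, fx$stays$stay_id)
  expect_equal(s2$total_los, fx$stays$total_los, tolerance = 1e-6)
  expect_equal(as.numeric(s2$ed_entry_time),
               round(as.numeric(fx$stays$ed_entry_time)))
  n2 <- read_notes(paths[["notes"]])
  expect_equal(length(n2), 15)
  expect_equal(n2[[3]]$sentences, fx$notes[[3]]$sentences)
  expect_equal(n2[[3]]$ground_truth, fx$notes[[3]]$ground_truth)
})

test_that("null cohorts decouple the outcome from severity", {
  cfg <- generator_config(n_stays = 600, seed = 5, severity_effect = 0)
  th <- generate_thesaurus(cfg)
  co <- generate_cohort(cfg, th)
  # severity no longer shifts LOS: correlation compatible with zero
  r <- cor(co$stays$latent_severity, log(co$stays$total_los))
  expect_lt(abs(r), 2.5 / sqrt(600))
})
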