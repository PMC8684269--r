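#' Configuration for the synthetic ED cohort generator
#'
#' Bundles and validates every tunable of the synthetic electronic health
#' record generator. Defaults emulate the published characteristics of a
#' one-hospital ED-admitted cohort: a long-tailed total length of stay
#' (LOS) with median around 6.5 days after the inclusion filter, near
#' balanced classes at the 7-day long-stay threshold, an ED LOS with median
#' 7.2 hours, 7.6% intensive-care stays, one near-ubiquitous clinical
#' concept (98.3% of stays), around 17 patient-affirmed concepts per note,
#' sparse diagnosis codes (most frequent about 4%), and 13% of stays with a
#' prior ED visit in the previous week.
#'
#' @param n_stays number of stays emitted after the inclusion filter.
#' @param seed integer master seed; all generator randomness derives from it.
#' @param los_meanlog,los_sdlog log-normal location and residual scale for
#'   total LOS in days, before the severity shift.
#' @param severity_effect strength of the latent-severity shift on log LOS.
#'   At 0 the outcome is independent of every feature (null cohort).
#' @param n_concepts total concepts in the generated thesaurus (>= 3).
#' @param n_informative_concepts concepts whose presence probability rises
#'   with latent severity; defaults to \code{min(12, n_concepts - 1)}.
#' @param ubiquitous_concept_prevalence target prevalence of the single
#'   near-ubiquitous concept.
#' @param mean_concepts_per_note target mean number of planted
#'   patient-affirmation concepts per note.
#' @param negation_rate,family_rate expected negated / family-context
#'   sentences per planted affirmation mention (fractions in [0, 1]).
#' @param second_visit_rate fraction of stays given a prior ED visit within
#'   7 days.
#' @param study_start,study_end calendar bounds of ED arrivals.
#' @param ed_los_meanlog,ed_los_sdlog log-normal parameters for ED LOS in
#'   hours.
#' @param icu_rate target fraction of intensive-care ward destinations.
#' @param language cue/terminology language for the notes ("en" or "fr").
#' @return an object of class \code{generator_config}.
#' @export
generator_config <- function(n_stays = 5000,
                             seed = 1,
                             los_meanlog = log(5.9),
                             los_sdlog = 0.55,
                             severity_effect = 0.6,
                             n_concepts = 60,
                             n_informative_concepts = NULL,
                             ubiquitous_concept_prevalence = 0.983,
                             mean_concepts_per_note = 17.2,
                             negation_rate = 0.10,
                             family_rate = 0.05,
                             second_visit_rate = 0.13,
                             study_start = "2019-01-01",
                             study_end = "2019-09-24",
                             ed_los_meanlog = log(7.2),
                             ed_los_sdlog = 0.5,
                             icu_rate = 0.076,
                             language = "en") {
  n_informative_concepts <- n_informative_concepts %||%
    min(12L, as.integer(n_concepts) - 1L)
  cfg <- list(n_stays = as.integer(n_stays), seed = as.integer(seed),
              los_meanlog = los_meanlog, los_sdlog = los_sdlog,
              severity_effect = severity_effect,
              n_concepts = as.integer(n_concepts),
              n_informative_concepts = as.integer(n_informative_concepts),
              ubiquitous_concept_prevalence = ubiquitous_concept_prevalence,
              mean_concepts_per_note = mean_concepts_per_note,
              negation_rate = negation_rate, family_rate = family_rate,
              second_visit_rate = second_visit_rate,
              study_start = as.character(study_start),
              study_end = as.character(study_end),
              ed_los_meanlog = ed_los_meanlog, ed_los_sdlog = ed_los_sdlog,
              icu_rate = icu_rate, language = match.arg(language, c("en", "fr")))
  if (cfg$n_stays < 1) stop("n_stays must be positive")
  if (cfg$n_concepts < 3) stop("n_concepts must be at least 3")
  if (cfg$n_informative_concepts > cfg$n_concepts)
    stop("n_informative_concepts must not exceed n_concepts")
  rates <- c(ubiquitous_concept_prevalence = cfg$ubiquitous_concept_prevalence,
             negation_rate = cfg$negation_rate, family_rate = cfg$family_rate,
             second_visit_rate = cfg$second_visit_rate, icu_rate = cfg$icu_rate)
  bad <- names(rates)[rates < 0 | rates > 1]
  if (length(bad)) stop("rate(s) outside [0,1]: ", paste(bad, collapse = ", "))
  if (as.Date(cfg$study_end) <= as.Date(cfg$study_start))
    stop("study window is empty")
  if (cfg$los_sdlog <= 0 || cfg$ed_los_sdlog <= 0)
    stop("scale parameters must be positive")
  structure(cfg, class = "generator_config")
}

# vocabulary for synthetic terms; stems are level-1 terms, modifiers build
# level-2 child terms ("abdominal pain" under "pain"). The synonym prefixes
# are reserved so a synonym only ever contains its own concept's term.
.stems <- c("pain", "fever", "cough", "nausea", "fracture", "bleeding",
            "dyspnea", "rash", "edema", "vertigo", "anemia", "sepsis",
            "asthma", "migraine", "palpitation", "seizure", "jaundice",
            "fatigue", "dehydration", "confusion")
.modifiers <- c("abdominal", "thoracic", "lumbar", "cervical", "femoral",
                "cranial", "pelvic", "ocular", "nasal", "dorsal", "frontal",
                "costal")
.syn_prefixes <- c("acute", "chronic")

#' Generate a toy hierarchical concept thesaurus
#'
#' Builds a deterministic synthetic thesaurus: a single root
#' ("clinical finding"), a level of base findings ("pain", "fever", ...),
#' and a level of site-qualified children whose term contains the parent's
#' term ("abdominal pain" under "pain") so that most-precise matching is
#' exercised. Roughly half the concepts carry one synonym formed by a
#' reserved prefix ("acute pain"), which contains the concept's own term
#' and therefore never collides with another concept.
#'
#' @param config a [generator_config()].
#' @return a [concept_thesaurus()]. Attributes \code{ubiquitous_id} (the
#'   concept planted near-ubiquitously, the first base finding) and
#'   \code{level} record generator ground truth.
#' @export
generate_thesaurus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_concepts
  max_n <- 1 + length(.stems) + length(.stems) * length(.modifiers)
  if (n > max_n) stop("n_concepts too large for the term vocabulary (max ",
                      max_n, ")")
  with_seed(derive_seed(config$seed, 1L), {
    n_stem <- min(n - 1L, length(.stems))
    n_child <- n - 1L - n_stem
    ids <- sprintf("C%03d", seq_len(n))
    term <- character(n); parent <- rep(NA_character_, n); level <- integer(n)
    term[1] <- "clinical finding"; level[1] <- 0L
    for (i in seq_len(n_stem)) {
      term[1 + i] <- .stems[i]
      parent[1 + i] <- ids[1]
      level[1 + i] <- 1L
    }
    if (n_child > 0) {
      combos <- expand.grid(stem = seq_len(n_stem),
                            mod = seq_along(.modifiers))
      combos <- combos[order(combos$mod, combos$stem), , drop = FALSE]
      for (j in seq_len(n_child)) {
        st <- combos$stem[j]; md <- combos$mod[j]
        term[1 + n_stem + j] <- paste(.modifiers[md], .stems[st])
        parent[1 + n_stem + j] <- ids[1 + st]
        level[1 + n_stem + j] <- 2L
      }
    }
    has_syn <- stats::runif(n) < 0.5
    has_syn[1] <- FALSE
    synonyms <- ifelse(has_syn,
                       paste(sample(.syn_prefixes, n, replace = TRUE), term),
                       "")
    th <- concept_thesaurus(data.frame(
      concept_id = ids, parent_id = parent, preferred_term = term,
      synonyms = synonyms, stringsAsFactors = FALSE))
    attr(th, "ubiquitous_id") <- ids[2]
    attr(th, "level") <- stats::setNames(level, ids)
    th
  })
}

.affirm_templates <- c(
  "patient reports %s since admission",
  "examination shows %s",
  "clinical course remarkable for %s",
  "ongoing %s this morning",
  "persistent %s on review",
  "%s at triage")
.neg_templates_en <- c("no %s", "denies %s", "negative for %s", "without %s")
.fam_templates_en <- c("mother has %s", "family history of %s",
                       "father treated for %s")
.famneg_templates_en <- c("family history negative for %s", "mother denies %s")
.neg_templates_fr <- c("pas de %s", "aucune %s", "sans %s")
.fam_templates_fr <- c("mere avec %s", "antecedents familiaux de %s")
.famneg_templates_fr <- c("antecedents familiaux sans %s")
.filler_sentences <- c("seen by the duty team", "vitals recorded at triage",
                       "plan discussed with patient", "awaiting ward bed",
                       "usual treatment continued")

# surface form of a concept for planting in a sentence: preferred term or a
# synonym, occasionally capitalized to exercise normalization
surface_form <- function(th, id) {
  row <- th$concepts[th$concepts$concept_id == id, ]
  forms <- c(row$preferred_term,
             if (nzchar(row$synonyms))
               strsplit(row$synonyms, "|", fixed = TRUE)[[1]])
  f <- sample(forms, 1)
  if (stats::runif(1) < 0.3) {
    substr(f, 1, 1) <- toupper(substr(f, 1, 1))
  }
  f
}

#' Generate a synthetic ED cohort with notes and ground truth
#'
#' Draws a cohort of ED-admitted hospital stays plus one free-text note
#' document per stay. A latent severity score per stay drives: the
#' log-normal total LOS (through \code{severity_effect}), the probability
#' of informative concepts appearing in the note, the CCMU triage code, the
#' intensive-care ward destination and (weakly) the GEMSA code and ED LOS,
#' so downstream models are learnable exactly when \code{severity_effect}
#' is positive. The inclusion rule of the emulated study is enforced: every
#' emitted stay spent more than two days in the post-ED ward (total LOS
#' minus ED time), and total LOS includes the ED time.
#'
#' Notes are sentence lists; each planted concept mention occupies its own
#' sentence built from templates free of thesaurus terms and context cues,
#' so extraction ground truth is exact. Negated and family-context
#' sentences are planted at the configured rates and recorded.
#'
#' @param config a [generator_config()].
#' @param thesaurus the matching [generate_thesaurus()] output.
#' @return list with elements \code{stays} (data.frame, one row per stay),
#'   \code{notes} (list of \code{stay_id}/\code{sentences}/
#'   \code{ground_truth}), and \code{config}.
#' @export
generate_cohort <- function(config, thesaurus) {
  stopifnot(inherits(config, "generator_config"),
            inherits(thesaurus, "concept_thesaurus"))
  with_seed(derive_seed(config$seed, 2L), {
    n <- config$n_stays
    level <- attr(thesaurus, "level")
    ubiq <- attr(thesaurus, "ubiquitous_id")
    if (is.null(ubiq)) {  # foreign thesaurus: pick the first non-root
      roots <- thesaurus$concepts$concept_id[is.na(thesaurus$parent)]
      ubiq <- setdiff(thesaurus$concepts$concept_id, roots)[1]
    }
    cids <- thesaurus$concepts$concept_id
    plantable <- setdiff(cids, cids[is.na(thesaurus$parent)])

    ## --- latent severity: partly age-driven so age carries signal ---
    age_z <- stats::rnorm(n)
    sev <- 0.3 * age_z + sqrt(1 - 0.3^2) * stats::rnorm(n)
    age <- pmin(pmax(round(64.3 + 26.3 * age_z), 0), 105)

    ## --- demographics ---
    gender <- ifelse(stats::runif(n) < 0.466, "M", "F")
    zip_pool <- sprintf("10%03d", c(0, 100, 150, 200, 300, 380, 400, 440,
                                    500, 600, 700, 800))
    zip_p <- (seq_along(zip_pool) + 2)^-1
    zip <- sample(zip_pool, n, replace = TRUE, prob = zip_p / sum(zip_p))

    ## --- arrivals with mild seasonal modulation ---
    t0 <- as.POSIXct(paste0(config$study_start, " 00:00:00"), tz = "UTC")
    t1 <- as.POSIXct(paste0(config$study_end, " 23:59:59"), tz = "UTC")
    span <- as.numeric(difftime(t1, t0, units = "secs"))
    entry <- rep(t0, n)
    need <- rep(TRUE, n)
    while (any(need)) {
      m <- sum(need)
      cand <- t0 + stats::runif(m, 0, span)
      doy <- as.numeric(format(cand, "%j"))
      accept <- stats::runif(m) < (1 + 0.3 * sin(2 * pi * doy / 365)) / 1.3
      entry[need][accept] <- cand[accept]
      need[need] <- !accept
    }

    ## --- ED stay ---
    ed_los <- exp(config$ed_los_meanlog + 0.1 * sev +
                    config$ed_los_sdlog * stats::rnorm(n))  # hours

    ## --- ward destination; intensive care probability rises with severity ---
    p_icu <- stats::plogis(stats::qlogis(config$icu_rate) * 1.13 + 0.9 * sev)
    icu <- stats::runif(n) < p_icu
    wards <- c("pulmonology", "digestive", "cardiovascular", "trauma_ortho",
               "neurology", "uro_nephrology", "rheumatology", "endocrinology",
               "hematology", "other_ward")
    ward_p <- c(17.4, 15.2, 10.0, 9.3, 9.3, 6.6, 6.3, 3.9, 3.9, 10.0)
    ward <- sample(wards, n, replace = TRUE, prob = ward_p / sum(ward_p))
    ward[icu] <- "intensive_care"

    ## --- triage codes ---
    ccmu_num <- pmin(pmax(round(3 + 1.1 * sev + stats::rnorm(n, 0, 0.9)), 1), 5)
    ccmu <- as.character(ccmu_num)
    u <- stats::runif(n)
    ccmu[u < 0.02] <- "P"
    ccmu[u >= 0.02 & u < 0.025] <- "D"
    gemsa <- as.character(pmin(pmax(round(3.5 + 0.5 * sev +
                                            stats::rnorm(n, 0, 1.5)), 1), 6))

    ## --- sparse ICD-10 primary diagnoses with a severity tilt ---
    n_codes <- 120
    letters_pool <- c("J", "R", "S", "M", "K", "I", "N", "E", "G", "A")
    code_len <- sample(3:5, n_codes, replace = TRUE, prob = c(0.3, 0.4, 0.3))
    codes <- sprintf("%s%s", sample(letters_pool, n_codes, replace = TRUE),
                     vapply(code_len, function(L)
                       paste(sample(0:9, L - 1, replace = TRUE),
                             collapse = ""), ""))
    codes <- make.unique(codes, sep = "")
    codes <- substr(codes, 1, 5)
    code_p <- 1 / (seq_len(n_codes) + 9)
    code_tilt <- sample(c(-1, 0, 1), n_codes, replace = TRUE,
                        prob = c(0.3, 0.4, 0.3))
    icd <- character(n)
    for (i in seq_len(n)) {
      w <- code_p * exp(0.8 * code_tilt * sev[i])
      icd[i] <- sample(codes, 1, prob = w / sum(w))
    }

    ## --- total LOS (days), truncated to the inclusion rule: more than two
    ##     days in the post-ED ward ---
    los <- exp(config$los_meanlog + config$severity_effect * sev +
                 config$los_sdlog * stats::rnorm(n))
    min_los <- 2 + ed_los / 24
    bad <- which(los <= min_los)
    guard <- 0
    while (length(bad) && guard < 1000) {
      los[bad] <- exp(config$los_meanlog + config$severity_effect * sev[bad] +
                        config$los_sdlog * stats::rnorm(length(bad)))
      bad <- bad[los[bad] <= min_los[bad]]
      guard <- guard + 1
    }
    if (length(bad)) los[bad] <- min_los[bad] * 1.05

    stays <- data.frame(
      stay_id = sprintf("S%05d", seq_len(n)),
      patient_id = sprintf("P%05d", seq_len(n)),
      age = age, gender = gender, zip_code = zip,
      ed_entry_time = entry, ed_exit_time = entry + ed_los * 3600,
      ed_los = ed_los, ward = ward, icu = icu,
      ccmu_raw = ccmu, gemsa = gemsa, icd10 = icd,
      total_los = los, latent_severity = sev,
      stringsAsFactors = FALSE)

    ## --- second visits: give a fraction of stays a prior ED entry within
    ##     7 days by re-dating a donor stay onto the same patient ---
    week <- 7 * 86400
    eligible <- which(as.numeric(difftime(entry, t0, units = "secs")) > week)
    n_flag <- min(floor(config$second_visit_rate * n),
                  length(eligible) %/% 2)
    if (n_flag > 0) {
      flagged <- sort(sample(eligible, n_flag))
      donors <- sample(setdiff(seq_len(n), flagged), n_flag)
      gap <- stats::runif(n_flag, 0.5, 6.9) * 86400
      stays$patient_id[donors] <- stays$patient_id[flagged]
      stays$ed_entry_time[donors] <- stays$ed_entry_time[flagged] - gap
      stays$ed_exit_time[donors] <- stays$ed_entry_time[donors] +
        stays$ed_los[donors] * 3600
    }

    ## --- concept prevalences; informative subset tracks severity ---
    q <- stats::setNames(rep(0, length(plantable)), plantable)
    q[ubiq] <- config$ubiquitous_concept_prevalence
    others <- setdiff(plantable, ubiq)
    base <- stats::rbeta(length(others), 1.2, 3)
    target_rest <- max(config$mean_concepts_per_note - q[ubiq], 0.5)
    base <- base * target_rest / sum(base)
    q[others] <- pmin(base, 0.95)
    informative <- if (config$n_informative_concepts > 0)
      sample(others, min(config$n_informative_concepts, length(others)))
    else character(0)
    slope <- 1.2
    # marginal-prevalence correction for the logistic-normal mixing
    a0 <- stats::qlogis(pmin(pmax(q, 1e-4), 1 - 1e-4))
    a0[informative] <- a0[informative] * sqrt(1 + 0.346 * slope^2)

    ## --- notes ---
    neg_t <- if (config$language == "en") .neg_templates_en else .neg_templates_fr
    fam_t <- if (config$language == "en") .fam_templates_en else .fam_templates_fr
    famneg_t <- if (config$language == "en") .famneg_templates_en
                else .famneg_templates_fr
    notes <- vector("list", n)
    for (i in seq_len(n)) {
      a <- a0
      a[informative] <- a[informative] + slope * sev[i]
      present <- plantable[stats::runif(length(plantable)) < stats::plogis(a)]
      sent <- character(0)
      gt <- list()
      for (cid in present) {
        sent <- c(sent, sprintf(sample(.affirm_templates, 1),
                                surface_form(thesaurus, cid)))
        gt[[length(gt) + 1]] <- c(cid, "patient", "affirmation")
      }
      n_neg <- stats::rbinom(1, max(length(present), 1), config$negation_rate)
      for (k in seq_len(n_neg)) {
        cid <- sample(plantable, 1)
        sent <- c(sent, sprintf(sample(neg_t, 1), surface_form(thesaurus, cid)))
        gt[[length(gt) + 1]] <- c(cid, "patient", "negation")
      }
      n_fam <- stats::rbinom(1, max(length(present), 1), config$family_rate)
      for (k in seq_len(n_fam)) {
        cid <- sample(plantable, 1)
        if (stats::runif(1) < 0.3) {
          sent <- c(sent, sprintf(sample(famneg_t, 1),
                                  surface_form(thesaurus, cid)))
          gt[[length(gt) + 1]] <- c(cid, "family", "negation")
        } else {
          sent <- c(sent, sprintf(sample(fam_t, 1),
                                  surface_form(thesaurus, cid)))
          gt[[length(gt) + 1]] <- c(cid, "family", "affirmation")
        }
      }
      sent <- c(sent, sample(.filler_sentences, sample(1:2, 1)))
      ord <- sample(seq_along(sent))
      gt_df <- if (length(gt)) {
        m <- do.call(rbind, gt)
        data.frame(concept_id = m[, 1], subject = m[, 2], polarity = m[, 3],
                   stringsAsFactors = FALSE)
      } else {
        data.frame(concept_id = character(0), subject = character(0),
                   polarity = character(0), stringsAsFactors = FALSE)
      }
      notes[[i]] <- list(stay_id = stays$stay_id[i], sentences = sent[ord],
                         ground_truth = gt_df)
    }

    list(stays = stays, notes = notes, config = config)
  })
}

#' Write a synthetic cohort to disk
#'
#' Persists the three artifacts in their interchange formats: the stay
#' table as CSV with ISO-8601 timestamps, the notes as JSON-lines (one
#' object per note: \code{stay_id}, \code{sentences}, \code{ground_truth}),
#' and the thesaurus as TSV.
#'
#' @param cohort output of [generate_cohort()].
#' @param thesaurus the matching thesaurus.
#' @param dir output directory (created if missing).
#' @return named character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, thesaurus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(stays = file.path(dir, "stays.csv"),
             notes = file.path(dir, "notes.jsonl"),
             thesaurus = file.path(dir, "thesaurus.tsv"))
  write_stays(cohort$stays, paths[["stays"]])
  write_notes(cohort$notes, paths[["notes"]])
  write_thesaurus(thesaurus, paths[["thesaurus"]])
  invisible(paths)
}

#' @rdname write_cohort
#' @param stays stay table data.frame.
#' @param path file path.
#' @export
write_stays <- function(stays, path) {
  out <- stays
  out$ed_entry_time <- format_time(out$ed_entry_time)
  out$ed_exit_time <- format_time(out$ed_exit_time)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_stays <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(stay_id = "character",
                                       patient_id = "character",
                                       zip_code = "character",
                                       ccmu_raw = "character",
                                       gemsa = "character",
                                       icd10 = "character"))
  df$ed_entry_time <- parse_time(df$ed_entry_time)
  df$ed_exit_time <- parse_time(df$ed_exit_time)
  df
}

#' @rdname write_cohort
#' @param notes list of note documents.
#' @export
write_notes <- function(notes, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (note in notes) {
    obj <- list(stay_id = jsonlite::unbox(as.character(note$stay_id)),
                sentences = as.character(note$sentences),
                ground_truth = note$ground_truth)
    writeLines(jsonlite::toJSON(obj, dataframe = "columns", null = "null"),
               con)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_notes <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lapply(lines, function(l) {
    obj <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    gt <- obj$ground_truth
    gt_df <- data.frame(concept_id = as.character(gt$concept_id %||% character(0)),
                        subject = as.character(gt$subject %||% character(0)),
                        polarity = as.character(gt$polarity %||% character(0)),
                        stringsAsFactors = FALSE)
    list(stay_id = obj$stay_id, sentences = as.character(obj$sentences),
         ground_truth = gt_df)
  })
}
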