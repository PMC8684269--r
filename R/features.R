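#' Parameters of the long-stay label and the srf concept filter
#'
#' The srf (symmetric relevance frequency) filter discards concepts whose
#' distribution over long and short stays is too balanced to carry signal.
#' The cutoff derives from the prevalence threshold \eqn{p}: a concept is
#' kept only if \eqn{srf > \log_2(2 + (1-p)/p)}; at the default
#' \eqn{p = 0.45} the cutoff is \eqn{\log_2(2 + 55/45) = 1.688}.
#'
#' @param long_stay_threshold_days LOS threshold (days) defining the long
#'   stay class; a stay of exactly the threshold is long. Default 7, the
#'   study threshold; 6 reflects the alternative reading of the cohort
#'   median.
#' @param prevalence_threshold class-prevalence threshold \eqn{p} in
#'   (0, 0.5).
#' @return object of class \code{srf_params}, with the derived
#'   \code{srf_cutoff}.
#' @export
srf_params <- function(long_stay_threshold_days = 7,
                       prevalence_threshold = 0.45) {
  if (long_stay_threshold_days <= 0)
    stop("long_stay_threshold_days must be positive")
  p <- prevalence_threshold
  if (!is.numeric(p) || p <= 0 || p >= 0.5)
    stop("prevalence_threshold must lie in (0, 0.5)")
  structure(list(long_stay_threshold_days = long_stay_threshold_days,
                 prevalence_threshold = p,
                 srf_cutoff = srf_cutoff(p)),
            class = "srf_params")
}

#' @rdname srf_params
#' @export
srf_cutoff <- function(prevalence_threshold = 0.45) {
  p <- prevalence_threshold
  log2(2 + (1 - p) / p)
}

#' Binary long-stay label
#'
#' @param total_los total LOS in days (vector); must be positive.
#' @param params an [srf_params()] (supplies the threshold), or a number.
#' @return integer vector of 0/1; 1 iff \code{total_los >= threshold}.
#' @export
label_long_stay <- function(total_los, params = srf_params()) {
  if (any(!is.finite(total_los) | total_los <= 0))
    stop("total_los must be positive")
  thr <- if (inherits(params, "srf_params"))
    params$long_stay_threshold_days else as.numeric(params)
  as.integer(total_los >= thr)
}

#' Symmetric relevance frequency score
#'
#' \deqn{srf = \log_2(2 + \max(a/\max(1,c),\; c/\max(1,a)))}
#' where \eqn{a} and \eqn{c} count the long and short stays containing the
#' concept. Symmetric in its arguments and always at least 1.
#'
#' @param a,c non-negative integer counts (vectorized).
#' @return numeric srf score(s).
#' @export
#' @examples
#' srf_score(55, 45)   # 1.688, the filter cutoff at p = 0.45
srf_score <- function(a, c) {
  if (any(a < 0) || any(c < 0) || any(a != floor(a)) || any(c != floor(c)))
    stop("a and c must be non-negative integers")
  log2(2 + pmax(a / pmax(1, c), c / pmax(1, a)))
}

#' Per-concept incidence counts over long and short stays
#'
#' @param stay_concepts named list: stay_id -> character vector of concept
#'   ids present for that stay.
#' @param labels 0/1 long-stay labels aligned with \code{stay_concepts}.
#' @return data.frame with columns \code{concept_id}, \code{a} (long stays
#'   containing the concept), \code{c} (short stays containing it).
#' @export
concept_incidence <- function(stay_concepts, labels) {
  stopifnot(length(stay_concepts) == length(labels))
  all_c <- unlist(stay_concepts, use.names = FALSE)
  lab_rep <- rep(as.integer(labels), lengths(stay_concepts))
  if (!length(all_c))
    return(data.frame(concept_id = character(0), a = integer(0),
                      c = integer(0), stringsAsFactors = FALSE))
  tab <- table(concept_id = all_c, long = factor(lab_rep, levels = 0:1))
  data.frame(concept_id = rownames(tab),
             a = as.integer(tab[, "1"]), c = as.integer(tab[, "0"]),
             stringsAsFactors = FALSE)
}

#' srf filter report and relevant-concept selection
#'
#' Scores every concept and keeps exactly those strictly above the cutoff;
#' a concept scoring exactly at the cutoff is non-relevant. Counts must be
#' computed on the training split only — selecting concepts on test data
#' would leak the outcome.
#'
#' @param incidence output of [concept_incidence()].
#' @param params an [srf_params()].
#' @return \code{srf_report()}: the incidence table with \code{srf} and
#'   logical \code{kept} columns. \code{filter_relevant_concepts()}: sorted
#'   character vector of kept concept ids.
#' @export
srf_report <- function(incidence, params = srf_params()) {
  if (!nrow(incidence)) {
    incidence$srf <- numeric(0); incidence$kept <- logical(0)
    return(incidence)
  }
  incidence$srf <- srf_score(incidence$a, incidence$c)
  incidence$kept <- incidence$srf > params$srf_cutoff
  incidence
}

#' @rdname srf_report
#' @export
filter_relevant_concepts <- function(incidence, params = srf_params()) {
  rep <- srf_report(incidence, params)
  sort(rep$concept_id[rep$kept])
}

#' Roll rare ICD-10 codes up the hierarchy
#'
#' Any code pooled over fewer than five stays is replaced by its parent —
#' the code with the last character removed — and the counts re-pooled;
#' the round is repeated to a fixed point. Truncation stops at three
#' characters regardless of count, so chapter-level information survives.
#' All codes are checked against the pooled counts at the start of each
#' round (so two rare siblings roll up together rather than one rescuing
#' the other).
#'
#' @param code_counts named non-negative numeric vector: code -> number of
#'   stays. Codes must be 3-5 characters.
#' @param min_count pooling threshold (default 5).
#' @return named character vector mapping every input code to its
#'   replacement code.
#' @export
#' @examples
#' rollup_icd10(c(M6289 = 3, M628 = 1, M62 = 0))  # all to "M62"
rollup_icd10 <- function(code_counts, min_count = 5) {
  codes <- names(code_counts)
  if (is.null(codes) || any(!nzchar(codes)))
    stop("code_counts must be a named vector")
  if (any(nchar(codes) < 3))
    stop("ICD-10 codes must have at least 3 characters: ",
         paste(codes[nchar(codes) < 3], collapse = ", "))
  if (any(code_counts < 0)) stop("counts must be non-negative")
  m <- stats::setNames(codes, codes)
  repeat {
    pooled <- tapply(as.numeric(code_counts), m[codes], sum)
    bad <- names(pooled)[pooled < min_count & nchar(names(pooled)) > 3]
    if (!length(bad)) break
    repl <- stats::setNames(substr(bad, 1, nchar(bad) - 1), bad)
    hit <- m %in% bad
    m[hit] <- repl[m[hit]]
  }
  m
}

#' CCMU triage code as a number
#'
#' Digits 1-5 map to themselves; the letter codes are mapped to the ends of
#' the ordinal scale: "D" (deceased on arrival) to 6 and "P" (psychiatric)
#' to 0.
#'
#' @param raw character vector over the alphabet \code{"1".."5","P","D"}.
#' @return integer vector.
#' @export
encode_ccmu <- function(raw) {
  raw <- as.character(raw)
  map <- c("1" = 1L, "2" = 2L, "3" = 3L, "4" = 4L, "5" = 5L,
           "D" = 6L, "P" = 0L)
  bad <- setdiff(unique(raw), names(map))
  if (length(bad))
    stop("illegal CCMU code(s): ", paste(bad, collapse = ", "))
  unname(map[raw])
}

#' Recent prior ED visit flag
#'
#' 1 iff the patient had at least one ED admission in the half-open window
#' \code{[entry - 7 days, entry)}; the index admission instant itself is
#' excluded.
#'
#' @param entry_time index ED entry (POSIXct or ISO-8601 string).
#' @param history the patient's prior ED entry timestamps (excluding the
#'   index stay). A "prior" admission after the index entry is an error.
#' @param window_days window length, default 7.
#' @return 0 or 1.
#' @export
recent_visit_flag <- function(entry_time, history, window_days = 7) {
  entry <- parse_time(entry_time)
  if (!length(history)) return(0L)
  hist <- parse_time(history)
  if (any(hist > entry))
    stop("history contains an admission after the index entry")
  lo <- entry - window_days * 86400
  as.integer(any(hist >= lo & hist < entry))
}

# cohort-level flags from the stay table itself: priors are earlier ED
# entries of the same patient
recent_visit_flags <- function(stays, window_days = 7) {
  entry <- parse_time(stays$ed_entry_time)
  out <- integer(nrow(stays))
  for (idx in split(seq_len(nrow(stays)), stays$patient_id)) {
    if (length(idx) < 2) next
    tt <- entry[idx]
    for (j in seq_along(idx)) {
      prior <- tt[tt < tt[j]]
      if (length(prior))
        out[idx[j]] <- as.integer(any(prior >= tt[j] - window_days * 86400))
    }
  }
  out
}

#' Prior 7-day ED admission counts
#'
#' For each admission, the number of cohort ED admissions in the half-open
#' window \code{[entry - 7 days, entry)} (the index instant excluded).
#'
#' @param entry_times cohort ED entry timestamps.
#' @param window_days window length, default 7.
#' @return integer vector aligned with \code{entry_times}.
#' @export
prior_admission_counts <- function(entry_times, window_days = 7) {
  t <- as.numeric(parse_time(entry_times))
  s <- sort(t)
  n_lt <- findInterval(t, s, left.open = TRUE)        # admissions < t
  n_lt_lo <- findInterval(t - window_days * 86400, s, left.open = TRUE)
  as.integer(n_lt - n_lt_lo)
}

#' Short-term ED activity index
#'
#' Rescales each stay's prior-7-day admission count by linear interpolation
#' between the cohort's 1st and 9th deciles of such counts: 0 at or below
#' the 1st decile, 1 at or above the 9th, linear in between. Deciles are
#' empirical quantiles with linear interpolation between order statistics.
#' The index uses timestamps only, never the outcome, so it is computed on
#' the whole cohort.
#'
#' @param entry_times cohort ED entry timestamps.
#' @param counts optional precomputed prior-admission counts.
#' @param window_days window length, default 7.
#' @return numeric vector in [0, 1]. If the two deciles coincide the
#'   distribution is degenerate and a constant 0.5 is returned with a
#'   warning.
#' @export
activity_index <- function(entry_times, counts = NULL, window_days = 7) {
  k <- counts %||% prior_admission_counts(entry_times, window_days)
  d <- stats::quantile(k, c(0.1, 0.9), names = FALSE, type = 7)
  if (d[1] == d[2]) {
    warning("degenerate prior-admission count distribution; ",
            "activity index set to 0.5 for all stays")
    return(rep(0.5, length(k)))
  }
  pmin(pmax((k - d[1]) / (d[2] - d[1]), 0), 1)
}

## ---- feature-matrix assembly ------------------------------------------

one_hot <- function(x, levels, prefix) {
  m <- matrix(0, nrow = length(x), ncol = length(levels),
              dimnames = list(NULL, paste0(prefix, levels)))
  hit <- match(as.character(x), levels)
  ok <- !is.na(hit)
  m[cbind(which(ok), hit[ok])] <- 1
  m
}

# map a raw ICD code through a training roll-up: exact, then progressively
# truncated; unknown prefixes fall outside every one-hot column
apply_rollup <- function(codes, mapping) {
  targets <- unique(unname(mapping))
  vapply(codes, function(cd) {
    if (cd %in% names(mapping)) return(unname(mapping[cd]))
    while (nchar(cd) >= 3) {
      if (cd %in% targets) return(cd)
      if (nchar(cd) == 3) break
      cd <- substr(cd, 1, nchar(cd) - 1)
    }
    NA_character_
  }, "", USE.NAMES = FALSE)
}

#' Assemble a model feature matrix for one feature set
#'
#' Builds the stays x features numeric matrix for one of the three feature
#' sets: \code{"common"} (age, gender, zip code, ED LOS, recent-visit flag,
#' short-term ED activity index, post-ED ward), \code{"structured"}
#' (common + CCMU numeric, GEMSA and rolled-up ICD-10 one-hot) and
#' \code{"unstructured"} (common + srf-relevant concept indicators).
#' Categorical variables are one-hot encoded; every data-driven encoding
#' decision (zip buckets, category levels, ICD roll-up counts, srf concept
#' selection) is fitted on the training rows only, and categories unseen in
#' training map to all-zero rows in their block.
#'
#' @param stays stay table (as generated or read with [read_stays()]).
#' @param stay_concepts named list stay_id -> concept ids (from
#'   [extract_stay_concepts()]); required for the unstructured set.
#' @param set one of \code{"common"}, \code{"structured"},
#'   \code{"unstructured"}.
#' @param train_ids stay ids forming the training split; defaults to all
#'   stays.
#' @param params an [srf_params()].
#' @param min_category_count categories (zip, ICD) rarer than this in
#'   training are pooled into an "other"/parent bucket. Default 5.
#' @return object of class \code{los_features}: list with \code{x} (numeric
#'   matrix), \code{y} (0/1 labels), \code{stay_ids}, \code{set},
#'   \code{train_ids}, and the fitted \code{encoder} description.
#' @export
build_feature_matrix <- function(stays, stay_concepts = NULL,
                                 set = c("common", "structured",
                                         "unstructured"),
                                 train_ids = NULL,
                                 params = srf_params(),
                                 min_category_count = 5) {
  set <- match.arg(set)
  ids <- as.character(stays$stay_id)
  train_ids <- if (is.null(train_ids)) ids else as.character(train_ids)
  tr <- ids %in% train_ids
  if (!any(tr)) stop("no training rows in `stays`")
  y <- label_long_stay(stays$total_los, params)

  entry <- parse_time(stays$ed_entry_time)
  ed_los <- stays$ed_los %||%
    as.numeric(difftime(parse_time(stays$ed_exit_time), entry,
                        units = "hours"))

  ## common block -- levels fitted on training rows
  zip_tab <- table(stays$zip_code[tr])
  zip_levels <- c(sort(names(zip_tab)[zip_tab >= min_category_count]),
                  "__other__")
  zip <- ifelse(stays$zip_code %in% zip_levels, stays$zip_code, "__other__")
  ward_levels <- sort(unique(stays$ward[tr]))
  gender_levels <- sort(unique(stays$gender[tr]))

  x <- cbind(age = as.numeric(stays$age),
             ed_los = ed_los,
             recent_visit = recent_visit_flags(stays),
             activity_index = activity_index(entry),
             one_hot(stays$gender, gender_levels, "gender_"),
             one_hot(zip, zip_levels, "zip_"),
             one_hot(stays$ward, ward_levels, "ward_"))
  encoder <- list(set = set, zip_levels = zip_levels,
                  ward_levels = ward_levels, gender_levels = gender_levels)

  if (set == "structured") {
    gemsa_levels <- sort(unique(stays$gemsa[tr]))
    icd_counts <- table(stays$icd10[tr])
    rollup <- rollup_icd10(stats::setNames(as.numeric(icd_counts),
                                           names(icd_counts)),
                           min_count = min_category_count)
    icd <- apply_rollup(stays$icd10, rollup)
    icd_levels <- sort(unique(stats::na.omit(icd[tr])))
    x <- cbind(x,
               ccmu = encode_ccmu(stays$ccmu_raw),
               one_hot(stays$gemsa, gemsa_levels, "gemsa_"),
               one_hot(icd, icd_levels, "icd_"))
    encoder$gemsa_levels <- gemsa_levels
    encoder$icd_rollup <- rollup
    encoder$icd_levels <- icd_levels
  } else if (set == "unstructured") {
    if (is.null(stay_concepts))
      stop("unstructured feature set requires `stay_concepts`")
    missing_ids <- setdiff(ids, names(stay_concepts))
    if (length(missing_ids))
      stop("stay_concepts missing entries for ",
           length(missing_ids), " stays")
    sc <- stay_concepts[ids]
    inc <- concept_incidence(sc[tr], y[tr])
    relevant <- filter_relevant_concepts(inc, params)
    cmat <- matrix(0, nrow = length(ids), ncol = length(relevant),
                   dimnames = list(NULL, paste0("concept_", relevant)))
    if (length(relevant)) {
      for (i in seq_along(ids)) {
        hit <- match(intersect(sc[[i]], relevant), relevant)
        if (length(hit)) cmat[i, hit] <- 1
      }
    }
    x <- cbind(x, cmat)
    encoder$relevant_concepts <- relevant
    encoder$srf_report <- srf_report(inc, params)
  }

  rownames(x) <- ids
  structure(list(x = x, y = y, stay_ids = ids, set = set,
                 train_ids = ids[tr], encoder = encoder, params = params),
            class = "los_features")
}

#' @export
print.los_features <- function(x, ...) {
  cat("<los_features> set='", x$set, "': ", nrow(x$x), " stays x ",
      ncol(x$x), " features; ", sum(x$y), " long stays (",
      round(100 * mean(x$y), 1), "%)\n", sep = "")
  invisible(x)
}
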