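# fixtures built in code and cached for the duration of one test run
fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = fixture_cache)) assign(key, fn(), fixture_cache)
  get(key, envir = fixture_cache)
}

# minimal hand-built thesaurus: root -> pain -> abdominal pain, root -> fever
toy_thesaurus <- function() {
  concept_thesaurus(data.frame(
    concept_id = c("root", "pain", "abd-pain", "fever"),
    parent_id = c(NA, "root", "pain", "root"),
    preferred_term = c("clinical finding", "pain", "abdominal pain", "fever"),
    synonyms = c("", "", "", "pyrexia"),
    stringsAsFactors = FALSE))
}

# small synthetic cohort shared across test files
demo_cohort <- function() {
  cached("demo_cohort", function() {
    cfg <- generator_config(n_stays = 250, seed = 42, n_concepts = 40,
                            n_informative_concepts = 10)
    th <- generate_thesaurus(cfg)
    co <- generate_cohort(cfg, th)
    list(cfg = cfg, th = th, stays = co$stays, notes = co$notes)
  })
}

# per-note ground-truth patient-affirmation concept sets
gt_affirmed <- function(notes) {
  out <- lapply(notes, function(n) {
    g <- n$ground_truth
    sort(unique(g$concept_id[g$subject == "patient" &
                               g$polarity == "affirmation"]))
  })
  names(out) <- vapply(notes, function(n) as.character(n$stay_id), "")
  out
}

# independent brute-force matcher: every term of every concept tried at
# every token position, no consumption, then most_precise
brute_match <- function(sentence, th) {
  toks <- strsplit(normalize_term(sentence), "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  found <- character(0)
  for (i in seq_len(nrow(th$concepts))) {
    row <- th$concepts[i, ]
    terms <- c(row$preferred_term,
               if (nzchar(row$synonyms))
                 strsplit(row$synonyms, "|", fixed = TRUE)[[1]])
    for (tm in normalize_term(terms)) {
      tt <- strsplit(tm, " ", fixed = TRUE)[[1]]
      k <- length(tt)
      if (k == 0 || k > length(toks)) next
      for (p in seq_len(length(toks) - k + 1)) {
        if (all(toks[p:(p + k - 1)] == tt)) {
          found <- c(found, row$concept_id)
          break
        }
      }
    }
  }
  most_precise(th, unique(found))
}

# independent fix-point roll-up: explicit per-round loops over targets
brute_rollup <- function(counts, min_count = 5) {
  m <- as.list(stats::setNames(names(counts), names(counts)))
  repeat {
    targets <- unique(unlist(m))
    pooled <- vapply(targets, function(tg)
      sum(counts[unlist(m) == tg]), 0)
    bad <- targets[pooled < min_count & nchar(targets) > 3]
    if (!length(bad)) return(unlist(m))
    for (nm in names(m))
      if (m[[nm]] %in% bad)
        m[[nm]] <- substr(m[[nm]], 1, nchar(m[[nm]]) - 1)
  }
}

# random ICD-like count table over a shared prefix pool
random_code_counts <- function(n_codes, seed) {
  set.seed(seed)
  prefixes <- c("M62", "J18", "R10", "S72", "K35")
  codes <- character(0)
  while (length(codes) < n_codes) {
    cd <- paste0(sample(prefixes, 1),
                 paste(sample(0:9, sample(0:2, 1), replace = TRUE),
                       collapse = ""))
    codes <- unique(c(codes, cd))
  }
  stats::setNames(rpois(length(codes), 3), codes)
}
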