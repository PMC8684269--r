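#' Configuration of an end-to-end pipeline run
#'
#' A single master seed deterministically derives every stage seed
#' (generation, splitting, tuning, fitting), so one integer reproduces a
#' whole run. The configuration round-trips losslessly through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param seed master integer seed.
#' @param generator a [generator_config()]; its own seed is overridden by a
#'   seed derived from \code{seed}.
#' @param srf an [srf_params()].
#' @param space a [search_space()].
#' @param cues_language cue lexicon language for extraction.
#' @param icu_subgroup run the intensive-care subgroup analysis too.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(seed = 1,
                       generator = generator_config(),
                       srf = srf_params(),
                       space = search_space(),
                       cues_language = c("en", "fr"),
                       icu_subgroup = FALSE) {
  stopifnot(inherits(generator, "generator_config"),
            inherits(srf, "srf_params"), inherits(space, "search_space"))
  generator$seed <- derive_seed(seed, 101L)
  structure(list(seed = as.integer(seed), generator = generator, srf = srf,
                 space = space,
                 cues_language = match.arg(cues_language),
                 icu_subgroup = isTRUE(icu_subgroup)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a \code{run_config}.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  obj <- list(seed = config$seed,
              generator = unclass(config$generator),
              srf = list(long_stay_threshold_days =
                           config$srf$long_stay_threshold_days,
                         prevalence_threshold =
                           config$srf$prevalence_threshold),
              space = unclass(config$space),
              cues_language = config$cues_language,
              icu_subgroup = config$icu_subgroup)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  gen <- obj$generator
  gen$seed <- NULL
  cfg <- run_config(
    seed = obj$seed,
    generator = do.call(generator_config, c(gen, list(seed = 0))),
    srf = do.call(srf_params, obj$srf),
    space = do.call(search_space, obj$space),
    cues_language = obj$cues_language,
    icu_subgroup = isTRUE(obj$icu_subgroup))
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> seed=", x$seed, ", n_stays=", x$generator$n_stays,
      ", severity_effect=", x$generator$severity_effect,
      ", search=", x$space$n_iterations, "x", x$space$n_folds,
      "-fold, lang=", x$cues_language, "\n", sep = "")
  invisible(x)
}

stage_outputs <- function(dir) list(
  simulate = file.path(dir, c("thesaurus.tsv", "stays.csv", "notes.jsonl")),
  extract = file.path(dir, c("mentions.csv", "stay_concepts.json")),
  features = file.path(dir, c("features_common.csv",
                              "features_structured.csv",
                              "features_unstructured.csv",
                              "srf_report.csv")),
  compare = file.path(dir, "report.json"))

#' Run the full pipeline: simulate, extract, features, compare
#'
#' Executes every stage in order, persisting each intermediate artifact
#' under \code{out_dir} and finishing with a manifest that records the
#' configuration, the master seed and an MD5 checksum of every artifact.
#' Two runs with the same configuration and seed produce byte-identical
#' artifacts and manifests. With \code{resume = TRUE}, a stage whose
#' outputs already exist is skipped unless an upstream stage was re-run.
#'
#' @param config a [run_config()].
#' @param out_dir writable output directory.
#' @param resume reuse existing stage outputs where possible.
#' @param quiet suppress per-stage progress messages.
#' @return the [run_comparison()] result, invisibly; artifacts on disk.
#' @export
run_all <- function(config, out_dir, resume = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outs <- stage_outputs(out_dir)
  say <- function(...) if (!quiet) message(...)
  ran <- c(simulate = FALSE, extract = FALSE, features = FALSE,
           compare = FALSE)
  must_run <- function(stage) {
    pos <- match(stage, names(ran))
    !resume || any(ran[seq_len(pos - 1)]) ||
      !all(file.exists(outs[[stage]]))
  }
  wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (must_run("simulate")) {
    say("[simulate] generating ", config$generator$n_stays, " stays")
    wrap("simulate", {
      th <- generate_thesaurus(config$generator)
      cohort <- generate_cohort(config$generator, th)
      write_cohort(cohort, th, out_dir)
    })
    ran["simulate"] <- TRUE
  } else say("[simulate] reusing existing artifacts")
  th <- read_thesaurus(outs$simulate[1])
  stays <- read_stays(outs$simulate[2])

  if (must_run("extract")) {
    say("[extract] scanning notes for ", nrow(th$concepts), " concepts")
    wrap("extract", {
      notes <- read_notes(outs$simulate[3])
      mentions <- extract_concepts(notes, th, default_cues(config$cues_language))
      utils::write.csv(mentions, outs$extract[1], row.names = FALSE)
      sets <- extract_stay_concepts(mentions, th)
      # keep stays without mentions too
      sets <- sets[as.character(vapply(notes, `[[`, "", "stay_id"))]
      names(sets) <- vapply(notes, `[[`, "", "stay_id")
      sets[vapply(sets, is.null, TRUE)] <- list(character(0))
      writeLines(jsonlite::toJSON(sets), outs$extract[2])
    })
    ran["extract"] <- TRUE
  } else say("[extract] reusing existing artifacts")
  stay_concepts <- lapply(jsonlite::fromJSON(
    paste(readLines(outs$extract[2]), collapse = "")), as.character)

  cmp_cfg <- comparison_config(seed = derive_seed(config$seed, 201L),
                               space = config$space, srf = config$srf,
                               icu_subgroup = config$icu_subgroup)
  split <- split_train_test(as.character(stays$stay_id),
                            cmp_cfg$train_fraction,
                            derive_seed(cmp_cfg$seed, 1L))

  if (must_run("features")) {
    say("[features] building common/structured/unstructured matrices")
    wrap("features", {
      for (set in c("common", "structured", "unstructured")) {
        fx <- build_feature_matrix(stays, stay_concepts, set,
                                   train_ids = split$train,
                                   params = config$srf)
        df <- cbind(data.frame(stay_id = fx$stay_ids,
                               long_stay = fx$y, stringsAsFactors = FALSE),
                    as.data.frame(fx$x))
        utils::write.csv(df, file.path(out_dir,
                                       paste0("features_", set, ".csv")),
                         row.names = FALSE)
        if (set == "unstructured")
          utils::write.csv(fx$encoder$srf_report, outs$features[4],
                           row.names = FALSE)
      }
    })
    ran["features"] <- TRUE
  } else say("[features] reusing existing artifacts")

  result <- NULL
  if (must_run("compare")) {
    say("[compare] tuning and fitting both models (",
        config$space$n_iterations, " candidates x ", config$space$n_folds,
        " folds)")
    result <- wrap("compare", {
      res <- run_comparison(stays, stay_concepts, cmp_cfg)
      writeLines(jsonlite::toJSON(comparison_to_list(res),
                                  auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE), outs$compare[1])
      for (m in c("structured", "unstructured"))
        utils::write.csv(res[[m]]$importances,
                         file.path(out_dir,
                                   paste0("importances_", m, ".csv")),
                         row.names = FALSE)
      res
    })
    ran["compare"] <- TRUE
  } else say("[compare] reusing existing artifacts")

  cfg_path <- file.path(out_dir, "config.yaml")
  write_run_config(config, cfg_path)
  files <- c(unlist(outs, use.names = FALSE),
             file.path(out_dir, c("importances_structured.csv",
                                  "importances_unstructured.csv")))
  files <- files[file.exists(files)]
  manifest <- list(seed = config$seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   artifacts = lapply(stats::setNames(files, basename(files)),
                                      function(f) unname(tools::md5sum(f))))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(result)
}

vio <- function(file, row, rule, message) {
  data.frame(file = file, row = row, rule = rule, message = message,
             stringsAsFactors = FALSE)
}

#' Validate pipeline input files
#'
#' Schema, alphabet, ordering and referential-integrity checks over the
#' three input artifacts. Returns every violation found (with row numbers)
#' rather than stopping at the first.
#'
#' @param stays_path stay table CSV.
#' @param notes_path notes JSON-lines.
#' @param thesaurus_path thesaurus TSV.
#' @return object of class \code{validation_report}: a data.frame of
#'   violations (zero rows when the inputs are clean).
#' @export
validate_inputs <- function(stays_path, notes_path, thesaurus_path) {
  for (p in c(stays_path, notes_path, thesaurus_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  v <- list()
  add <- function(x) v[[length(v) + 1]] <<- x

  stays <- tryCatch(read_stays(stays_path), error = function(e) e)
  if (inherits(stays, "error")) {
    add(vio(stays_path, NA, "schema", conditionMessage(stays)))
    stays <- NULL
  } else {
    need <- c("stay_id", "patient_id", "age", "gender", "zip_code",
              "ed_entry_time", "ed_exit_time", "ward", "ccmu_raw",
              "gemsa", "icd10", "total_los")
    miss <- setdiff(need, names(stays))
    if (length(miss))
      add(vio(stays_path, NA, "schema",
              paste("missing column(s):", paste(miss, collapse = ", "))))
    else {
      bad <- which(!(stays$ed_exit_time > stays$ed_entry_time))
      for (r in bad) add(vio(stays_path, r, "timestamp_order",
                             "ed_exit_time not after ed_entry_time"))
      bad <- which(!(stays$total_los > 0))
      for (r in bad) add(vio(stays_path, r, "positive_los",
                             "total_los must be positive"))
      alphabet <- c(as.character(1:5), "P", "D")
      bad <- which(!stays$ccmu_raw %in% alphabet)
      for (r in bad) add(vio(stays_path, r, "ccmu_alphabet",
                             paste("illegal CCMU value:", stays$ccmu_raw[r])))
      bad <- which(!stays$gemsa %in% as.character(1:6))
      for (r in bad) add(vio(stays_path, r, "gemsa_alphabet",
                             paste("illegal GEMSA value:", stays$gemsa[r])))
      bad <- which(!grepl("^[A-Za-z0-9]{3,5}$", stays$icd10))
      for (r in bad) add(vio(stays_path, r, "icd10_format",
                             paste("malformed ICD-10 code:", stays$icd10[r])))
      if (anyDuplicated(stays$stay_id))
        add(vio(stays_path, NA, "unique_id", "duplicated stay_id"))
    }
  }

  th <- tryCatch(read_thesaurus(thesaurus_path), error = function(e) e)
  if (inherits(th, "error"))
    add(vio(thesaurus_path, NA, "thesaurus", conditionMessage(th)))

  notes <- tryCatch(read_notes(notes_path), error = function(e) e)
  if (inherits(notes, "error")) {
    add(vio(notes_path, NA, "json", conditionMessage(notes)))
  } else if (!is.null(stays)) {
    known <- stays$stay_id
    for (i in seq_along(notes)) {
      sid <- notes[[i]]$stay_id
      if (!sid %in% known)
        add(vio(notes_path, i, "referential",
                paste("note references unknown stay_id:", sid)))
    }
  }

  out <- if (length(v)) do.call(rbind, v) else
    vio(character(0), integer(0), character(0), character(0))
  class(out) <- c("validation_report", class(out))
  out
}

#' @export
print.validation_report <- function(x, ...) {
  if (!nrow(x)) cat("validation: clean (no violations)\n")
  else {
    cat("validation:", nrow(x), "violation(s)\n")
    print.data.frame(utils::head(as.data.frame(x), 20))
  }
  invisible(x)
}
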