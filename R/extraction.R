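#' Split free text into sub-texts
#'
#' First step of the note-processing pipeline: the free text is cut into
#' sentence-level sub-texts on terminal punctuation (\code{. ! ? ;}) and
#' newlines. Empty fragments are dropped; all non-delimiter characters are
#' preserved in order.
#'
#' @param text a single character string (empty allowed).
#' @return character vector of sub-texts, possibly empty.
#' @export
#' @examples
#' split_subtexts("No fever. Abdominal pain reported.")
split_subtexts <- function(text) {
  stopifnot(length(text) == 1)
  if (is.na(text) || !nzchar(text)) return(character(0))
  parts <- strsplit(text, "[.!?;\n\r]+")[[1]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Negation and family-context cue configuration
#'
#' The context classifier is cue-based with sentence scope: a sub-text is
#' family-related iff any family cue occurs in it, and negated iff any
#' negation cue occurs; the two axes are independent and absence of cues
#' yields the patient-affirmation label (neutral text counts as
#' affirmation). Cues are normalized like thesaurus terms and matched at
#' token boundaries; multi-word cues are allowed.
#'
#' @param negation character vector of negation cues.
#' @param family character vector of family cues.
#' @return an object of class \code{cue_config}.
#' @seealso [default_cues()] for the bundled English and French lexicons.
#' @export
cue_config <- function(negation, family) {
  negation <- unique(normalize_term(negation))
  family <- unique(normalize_term(family))
  negation <- negation[nzchar(negation)]
  family <- family[nzchar(family)]
  if (!length(negation) || !length(family))
    stop("cue lists must be non-empty")
  structure(list(negation = negation, family = family, scope = "sentence"),
            class = "cue_config")
}

#' Default cue lexicons
#'
#' Small default negation/family cue lists. They are deliberately compact:
#' the classifier contract is language-agnostic given the lexicons, and
#' production use should supply a locally curated list.
#'
#' @param language \code{"en"} or \code{"fr"}.
#' @return a [cue_config()].
#' @export
default_cues <- function(language = c("en", "fr")) {
  language <- match.arg(language)
  if (language == "en") {
    cue_config(
      negation = c("no", "not", "denies", "denied", "without", "negative for",
                   "free of", "absence of"),
      family = c("mother", "father", "sister", "brother", "family",
                 "family history", "parent", "grandmother", "grandfather")
    )
  } else {
    cue_config(
      negation = c("pas de", "aucun", "aucune", "sans", "absence de", "ni",
                   "negatif pour", "nie"),
      family = c("mere", "pere", "soeur", "frere", "famille",
                 "antecedents familiaux", "parent", "grand-mere", "grand-pere")
    )
  }
}

tokenize <- function(x) {
  toks <- strsplit(x, "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

# does the cue token sequence occur in toks?
has_cue <- function(toks, cue_tok_list) {
  nt <- length(toks)
  for (ct in cue_tok_list) {
    k <- length(ct)
    if (k == 0 || k > nt) next
    if (k == 1) {
      if (ct %in% toks) return(TRUE)
    } else {
      for (i in seq_len(nt - k + 1))
        if (all(toks[i:(i + k - 1)] == ct)) return(TRUE)
    }
  }
  FALSE
}

#' Classify the context of a sub-text
#'
#' Second pipeline step: assigns one of four context labels —
#' patient/family crossed with affirmation/negation. Neutral text (no cue)
#' is patient-affirmation.
#'
#' @param subtext a single character string.
#' @param cues a [cue_config()].
#' @return a list with elements \code{subject} (\code{"patient"} or
#'   \code{"family"}) and \code{polarity} (\code{"affirmation"} or
#'   \code{"negation"}).
#' @export
#' @examples
#' classify_context("no fever", default_cues("en"))
classify_context <- function(subtext, cues) {
  stopifnot(inherits(cues, "cue_config"))
  toks <- tokenize(normalize_term(subtext))
  neg <- has_cue(toks, strsplit(cues$negation, " ", fixed = TRUE))
  fam <- has_cue(toks, strsplit(cues$family, " ", fixed = TRUE))
  list(subject = if (fam) "family" else "patient",
       polarity = if (neg) "negation" else "affirmation")
}

# scan one tokenized sub-text against the thesaurus term table.
# Longest terms claim their tokens first; within a token-length class
# candidates are taken by earliest start, then concept_id. Tokens are
# consumed, so "abdominal pain" blocks a second match of "pain" on the
# same tokens. Returns data.frame(concept_id, term, start).
scan_tokens <- function(toks, th) {
  nt <- length(toks)
  empty <- data.frame(concept_id = character(0), term = character(0),
                      start = integer(0), stringsAsFactors = FALSE)
  if (nt == 0) return(empty)
  tv_term <- th$terms$term; tv_cid <- th$terms$concept_id
  tv_k <- th$terms$n_tokens; tv_tok <- th$terms$tokens
  keep <- tv_k <= nt & th$terms$first_token %in% toks
  if (!any(keep)) return(empty)
  idx <- which(keep)
  consumed <- logical(nt)
  h_cid <- character(0); h_term <- character(0); h_start <- integer(0)
  for (k in sort(unique(tv_k[idx]), decreasing = TRUE)) {
    js <- idx[tv_k[idx] == k]
    c_start <- integer(0); c_j <- integer(0)
    for (j in js) {
      tt <- tv_tok[[j]]
      if (k == 1L) {
        pos <- which(toks == tt)
      } else {
        pos <- integer(0)
        for (i in seq_len(nt - k + 1))
          if (all(toks[i:(i + k - 1)] == tt)) pos <- c(pos, i)
      }
      if (length(pos)) {
        c_start <- c(c_start, pos)
        c_j <- c(c_j, rep(j, length(pos)))
      }
    }
    if (!length(c_start)) next
    ord <- order(c_start, tv_cid[c_j])
    for (m in ord) {
      span <- c_start[m]:(c_start[m] + k - 1)
      if (any(consumed[span])) next
      consumed[span] <- TRUE
      h_cid <- c(h_cid, tv_cid[c_j[m]])
      h_term <- c(h_term, tv_term[c_j[m]])
      h_start <- c(h_start, c_start[m])
    }
  }
  data.frame(concept_id = h_cid, term = h_term, start = h_start,
             stringsAsFactors = FALSE)
}

#' Match thesaurus concepts in a sub-text
#'
#' Third pipeline step, for one sub-text: a concept matches iff one of its
#' normalized terms occurs as a whole-token sequence in the normalized
#' sub-text. Longer terms claim their tokens first (longest-match
#' precedence, ties by earliest start then concept id) and matched tokens
#' are not reused within the scan. The matched set is then reduced with
#' [most_precise()], so an ancestor matched alongside its descendant is
#' dropped.
#'
#' @param subtext a single character string.
#' @param th a [concept_thesaurus()].
#' @return character vector of concept ids (a set, sorted).
#' @export
#' @examples
#' th <- concept_thesaurus(data.frame(
#'   concept_id = c("C1", "C2"), parent_id = c(NA, "C1"),
#'   preferred_term = c("pain", "abdominal pain"), synonyms = ""))
#' match_concepts("diffuse abdominal pain", th)
match_concepts <- function(subtext, th) {
  stopifnot(inherits(th, "concept_thesaurus"))
  hits <- scan_tokens(tokenize(normalize_term(subtext)), th)
  most_precise(th, unique(hits$concept_id))
}

#' Extract all concept mentions from note documents
#'
#' Runs the full three-step pipeline over a collection of note documents
#' and returns one row per concept mention, with its context label. Every
#' sub-text is scanned (so negated/family mentions are visible in the
#' output table), but only patient-affirmation mentions contribute to the
#' stay-level concept sets (see [extract_stay_concepts()]).
#'
#' @param notes list of note documents; each is a list with \code{stay_id}
#'   and \code{sentences} (character vector). Raw note text is also
#'   accepted in a \code{text} field and split with [split_subtexts()].
#' @param th a [concept_thesaurus()].
#' @param cues a [cue_config()].
#' @return data.frame with columns \code{stay_id}, \code{sentence_index},
#'   \code{concept_id}, \code{subject}, \code{polarity},
#'   \code{matched_term}.
#' @export
extract_concepts <- function(notes, th, cues = default_cues("en")) {
  stopifnot(inherits(th, "concept_thesaurus"), inherits(cues, "cue_config"))
  neg_toks <- strsplit(cues$negation, " ", fixed = TRUE)
  fam_toks <- strsplit(cues$family, " ", fixed = TRUE)
  a_stay <- list(); a_sent <- list(); a_cid <- list()
  a_subj <- list(); a_pol <- list(); a_term <- list()
  p <- 0L
  for (i in seq_along(notes)) {
    note <- notes[[i]]
    sents <- if (!is.null(note$sentences)) as.character(note$sentences)
             else split_subtexts(note$text)
    if (!length(sents)) next
    toks_all <- strsplit(normalize_term(sents), "[^a-z0-9]+")
    for (s in seq_along(sents)) {
      toks <- toks_all[[s]]
      toks <- toks[nzchar(toks)]
      hits <- scan_tokens(toks, th)
      if (!nrow(hits)) next
      kept <- most_precise(th, unique(hits$concept_id))
      sel <- hits$concept_id %in% kept
      nh <- sum(sel)
      p <- p + 1L
      a_stay[[p]] <- rep(as.character(note$stay_id), nh)
      a_sent[[p]] <- rep(s, nh)
      a_cid[[p]] <- hits$concept_id[sel]
      a_subj[[p]] <- rep(if (has_cue(toks, fam_toks)) "family" else "patient",
                         nh)
      a_pol[[p]] <- rep(if (has_cue(toks, neg_toks)) "negation"
                        else "affirmation", nh)
      a_term[[p]] <- hits$term[sel]
    }
  }
  data.frame(stay_id = unlist(a_stay) %||% character(0),
             sentence_index = as.integer(unlist(a_sent)),
             concept_id = unlist(a_cid) %||% character(0),
             subject = unlist(a_subj) %||% character(0),
             polarity = unlist(a_pol) %||% character(0),
             matched_term = unlist(a_term) %||% character(0),
             stringsAsFactors = FALSE)
}

#' Stay-level concept sets from patient-affirmation sub-texts
#'
#' Reduces extracted mentions to one binary concept set per stay: the union
#' of matched concepts over exactly the sub-texts labelled
#' patient-affirmation. Concepts appearing only in negated or
#' family-related sub-texts are absent. Only presence is kept — a concept
#' mentioned ten times counts once.
#'
#' @param notes list of note documents (see [extract_concepts()]), or a
#'   mentions data.frame already produced by it.
#' @param th a [concept_thesaurus()].
#' @param cues a [cue_config()].
#' @return named list: stay_id -> sorted character vector of concept ids.
#'   Stays whose notes yield no concept get an empty vector.
#' @export
extract_stay_concepts <- function(notes, th, cues = default_cues("en")) {
  mentions <- if (is.data.frame(notes)) notes else
    extract_concepts(notes, th, cues)
  aff <- mentions[mentions$subject == "patient" &
                    mentions$polarity == "affirmation", , drop = FALSE]
  ids <- if (is.data.frame(notes)) unique(mentions$stay_id)
         else vapply(notes, function(n) as.character(n$stay_id), "")
  by_stay <- split(aff$concept_id, aff$stay_id)
  sets <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    v <- by_stay[[id]]
    sets[[id]] <- if (is.null(v)) character(0) else sort(unique(v))
  }
  sets
}
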