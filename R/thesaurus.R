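#' Normalize a clinical term or sentence for exact matching
#'
#' Applies the normalization dialect used throughout the package for "exact"
#' dictionary matching: case-folding, accent-folding (so French clinical text
#' matches unaccented dictionary entries and vice versa), collapsing of
#' internal whitespace, and trimming. Matching is performed on normalized
#' text on both sides, so a thesaurus entry \code{"Douleur Abdominale"} and
#' note text \code{"douleur  abdominale"} agree.
#'
#' @param x character vector.
#' @return character vector of the same length, normalized.
#' @export
#' @examples
#' normalize_term(c("  Douleur  Abdominale ", "FIEVRE"))
normalize_term <- function(x) {
  out <- tolower(enc2utf8(as.character(x)))
  # explicit accent map: locale-independent, unlike iconv transliteration
  out <- gsub("œ", "oe", out, fixed = TRUE)
  out <- gsub("æ", "ae", out, fixed = TRUE)
  out <- chartr("áàâäãåçéèêëíìîïñóòôöõúùûüýÿ",
                "aaaaaaceeeeiiiinooooouuuuyy", out)
  out <- gsub("\\s+", " ", out)
  trimws(out)
}

#' Construct a hierarchical concept thesaurus
#'
#' Builds the in-memory thesaurus used by concept extraction: a single-parent
#' rooted hierarchy of concepts, each carrying a preferred term and optional
#' synonyms. All terms are normalized (see [normalize_term()]) and indexed;
#' a normalized term may belong to exactly one concept.
#'
#' @param concepts data.frame with columns \code{concept_id},
#'   \code{parent_id} (\code{NA} or \code{""} for a root),
#'   \code{preferred_term} and \code{synonyms} (pipe-separated string,
#'   possibly empty).
#' @return an object of class \code{concept_thesaurus}.
#' @details Validation rejects duplicated concept ids, parent references to
#'   unknown concepts, cycles in the parent chain, empty terms after
#'   normalization, and any normalized term mapped to two different concepts
#'   (the error names both). Multi-parent concepts are not representable:
#'   the hierarchy is a forest of single-parent trees.
#' @export
concept_thesaurus <- function(concepts) {
  req <- c("concept_id", "parent_id", "preferred_term", "synonyms")
  if (!is.data.frame(concepts) || !all(req %in% names(concepts)))
    stop("`concepts` must be a data.frame with columns ",
         paste(req, collapse = ", "))
  concepts <- as.data.frame(concepts)[, req]
  concepts$concept_id <- as.character(concepts$concept_id)
  concepts$parent_id <- as.character(concepts$parent_id)
  concepts$parent_id[is.na(concepts$parent_id) | concepts$parent_id == ""] <- NA_character_
  concepts$preferred_term <- as.character(concepts$preferred_term)
  concepts$synonyms <- as.character(concepts$synonyms)
  concepts$synonyms[is.na(concepts$synonyms)] <- ""

  if (anyDuplicated(concepts$concept_id))
    stop("duplicated concept_id: ",
         paste(unique(concepts$concept_id[duplicated(concepts$concept_id)]),
               collapse = ", "))
  unknown <- setdiff(stats::na.omit(concepts$parent_id), concepts$concept_id)
  if (length(unknown))
    stop("parent_id refers to unknown concept(s): ",
         paste(unknown, collapse = ", "))

  parent <- stats::setNames(concepts$parent_id, concepts$concept_id)
  # cycle check: walk each parent chain, it must end at a root within n steps
  n <- nrow(concepts)
  for (id in concepts$concept_id) {
    cur <- id
    for (step in seq_len(n + 1)) {
      cur <- parent[[cur]]
      if (is.na(cur)) break
      if (identical(cur, id) || step > n)
        stop("cycle detected in parent chain at concept ", id)
    }
  }

  terms <- do.call(rbind, lapply(seq_len(n), function(i) {
    syn <- concepts$synonyms[i]
    tt <- c(concepts$preferred_term[i],
            if (nzchar(syn)) strsplit(syn, "|", fixed = TRUE)[[1]])
    tt <- unique(normalize_term(tt))
    tt <- tt[nzchar(tt)]
    if (!length(tt))
      stop("concept ", concepts$concept_id[i], " has no non-empty term")
    data.frame(term = tt, concept_id = concepts$concept_id[i],
               stringsAsFactors = FALSE)
  }))
  dup <- terms$term[duplicated(terms$term)]
  if (length(dup)) {
    d <- unique(dup)[1]
    owners <- unique(terms$concept_id[terms$term == d])
    if (length(owners) > 1)
      stop("term '", d, "' maps to two concepts: ",
           paste(owners, collapse = " and "))
    terms <- terms[!duplicated(terms$term), ]
  }
  tok <- strsplit(terms$term, " ", fixed = TRUE)
  terms$n_tokens <- lengths(tok)
  terms$first_token <- vapply(tok, `[`, "", 1)
  # longest-match precedence: order terms by token count desc, then term,
  # then concept id, so scanning is deterministic
  ord <- order(-terms$n_tokens, terms$term, terms$concept_id)
  terms <- terms[ord, ]
  rownames(terms) <- NULL
  terms$tokens <- tok[ord]

  structure(list(
    concepts = concepts,
    parent = parent,
    has_children = stats::setNames(concepts$concept_id %in%
                                     stats::na.omit(concepts$parent_id),
                                   concepts$concept_id),
    terms = terms
  ), class = "concept_thesaurus")
}

#' @export
print.concept_thesaurus <- function(x, ...) {
  n_root <- sum(is.na(x$parent))
  cat("<concept_thesaurus> ", nrow(x$concepts), " concepts (",
      sum(!x$has_children), " leaves, ", n_root, " root",
      if (n_root != 1) "s", "), ", nrow(x$terms), " indexed terms\n", sep = "")
  invisible(x)
}

check_known <- function(th, ids) {
  unknown <- setdiff(ids, th$concepts$concept_id)
  if (length(unknown))
    stop("unknown concept id(s): ", paste(unknown, collapse = ", "))
}

#' Is a concept a leaf of the hierarchy?
#'
#' @param th a [concept_thesaurus()].
#' @param id concept id(s).
#' @return logical vector: \code{TRUE} where no concept lists \code{id}
#'   as its parent.
#' @export
is_leaf <- function(th, id) {
  check_known(th, id)
  !th$has_children[as.character(id)]
}

#' Proper ancestors of a concept
#'
#' @param th a [concept_thesaurus()].
#' @param id a single concept id.
#' @return character vector of ancestor ids from parent to root
#'   (empty for a root).
#' @export
concept_ancestors <- function(th, id) {
  check_known(th, id)
  out <- character(0)
  cur <- th$parent[[as.character(id)]]
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- th$parent[[cur]]
  }
  out
}

#' Reduce a matched concept set to its most precise members
#'
#' Drops every concept that is a proper ancestor of another member of the
#' set, mirroring how a concept hierarchy is used to keep only the most
#' specific extraction: if both "pain" and "abdominal pain" matched a
#' sentence, only "abdominal pain" is retained. Concepts with no
#' ancestor/descendant relation are both kept, as is a matched non-leaf
#' with no matched descendant.
#'
#' @param th a [concept_thesaurus()].
#' @param matched character vector (treated as a set) of concept ids.
#' @return character vector: the subset of \code{matched} with all proper
#'   ancestors of other members removed, sorted for determinism.
#' @export
most_precise <- function(th, matched) {
  matched <- unique(as.character(matched))
  if (!length(matched)) return(character(0))
  check_known(th, matched)
  anc <- unique(unlist(lapply(matched, concept_ancestors, th = th)))
  sort(setdiff(matched, anc))
}

#' Read a thesaurus from its TSV representation
#'
#' The on-disk format is a tab-separated file with header columns
#' \code{concept_id}, \code{parent_id} (empty for a root),
#' \code{preferred_term}, \code{synonyms} (pipe-separated, possibly empty).
#' Any thesaurus of this shape can be used; the bundled synthetic generator
#' writes one, and a licensed vocabulary subset exported to the same shape
#' drops in unchanged.
#'
#' @param path file path.
#' @return a [concept_thesaurus()].
#' @export
read_thesaurus <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          quote = "", fileEncoding = "UTF-8")
  concept_thesaurus(df)
}

#' Write a thesaurus to TSV
#'
#' @param th a [concept_thesaurus()].
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_thesaurus <- function(th, path) {
  df <- th$concepts
  df$parent_id[is.na(df$parent_id)] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
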