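## Free-text medication entries -> subject x drug-class Boolean matrix:
## normalization, approximate lexicon matching with confidence scores,
## manual-review decisions, ingredient mapping, class rollup.

## tokens stripped during normalization (units, routes, frequencies)
.med_stopwords <- c("mg", "mcg", "ug", "g", "gm", "ml", "l", "iu", "u",
                    "meq", "units", "unit", "tab", "tabs", "tablet",
                    "tablets", "cap", "caps", "capsule", "capsules",
                    "qd", "bid", "tid", "qid", "qhs", "qod", "prn", "po",
                    "od", "hs", "daily", "weekly", "nightly", "oral")

#' Normalize a free-text medication entry into drug-name tokens
#'
#' Lowercases, splits combination separators (`/`, `+`, `" with "`) into
#' multiple tokens, strips doses, units, routes and frequencies
#' (numbers, `mg`, `mcg`, `ml`, `iu`, `qd`, `bid`, ...) and collapses
#' whitespace.  Text that reduces to nothing yields zero tokens.
#'
#' @param raw_text free-text medication string
#' @return character vector of normalized drug-name tokens (possibly
#'   empty)
#' @export
normalize_med_text <- function(raw_text) {
  stopifnot(length(raw_text) == 1)
  txt <- tolower(trimws(raw_text))
  if (!nzchar(txt)) stop2("empty medication text")
  txt <- gsub(" with ", "/", txt, fixed = TRUE)
  parts <- strsplit(txt, "[/+]")[[1]]
  out <- character()
  for (p in parts) {
    words <- strsplit(trimws(p), "[[:space:]]+")[[1]]
    keep <- vapply(words, function(w) {
      if (grepl("^[0-9][-0-9.,]*$", w)) return(FALSE)        # bare dose
      if (grepl("^[0-9][-0-9.,]*[a-z%]+$", w)) return(FALSE) # dose+unit
      if (w %in% .med_stopwords) return(FALSE)
      nzchar(w)
    }, logical(1))
    tok <- paste(words[keep], collapse = " ")
    tok <- gsub("[[:space:]]+", " ", trimws(tok))
    if (nzchar(tok)) out <- c(out, tok)
  }
  out
}

#' Normalized-Levenshtein string scorer
#'
#' Default matcher backend: `1 - d / max(nchar)` where `d` is the
#' Levenshtein edit distance.  Scores 1 for an exact match, is symmetric,
#' and decreases with edit distance.
#'
#' @param query normalized token
#' @param candidates character vector of lexicon names
#' @return numeric scores in `[0, 1]`
#' @export
levenshtein_matcher <- function(query, candidates) {
  d <- utils::adist(query, candidates)[1, ]
  1 - d / pmax(nchar(query), nchar(candidates))
}

#' Load a drug lexicon
#'
#' JSON with two maps: `drugs` (normalized brand or generic name ->
#' ingredient id list) and `ingredients` (ingredient id -> list of
#' `{class, source}` records with source in NDFRT/ATC/MESH/DAILYMED/
#' FDASPL).
#'
#' @param path JSON file; default: the bundled synthetic offline lexicon
#'   (a stand-in for live terminology services)
#' @return object of class `term_lexicon`
#' @export
read_lexicon <- function(path = system.file("extdata",
                                            "synthetic_med_lexicon.json",
                                            package = "p180curate")) {
  lx <- jsonlite::read_json(path)
  if (!all(c("drugs", "ingredients") %in% names(lx)))
    stop2("lexicon needs 'drugs' and 'ingredients' maps")
  lx$drugs <- lapply(lx$drugs, unlist)
  referenced <- unique(unlist(lx$drugs))
  orphan <- setdiff(referenced, names(lx$ingredients))
  if (length(orphan))
    stop2("lexicon ingredient(s) without class entry: ",
          paste(orphan, collapse = ", "))
  structure(lx, class = "term_lexicon")
}

#' Drug classes bundled as the default analysis set
#'
#' @return data.frame (`class`, `source`) of drug classes with their
#'   source terminologies
#' @export
default_drug_classes <- function() {
  utils::read.csv(system.file("extdata", "drug_classes.csv",
                              package = "p180curate"),
                  stringsAsFactors = FALSE, check.names = FALSE)
}

#' Match one normalized token against the lexicon
#'
#' Candidates are ranked by matcher score (descending, ties broken
#' lexicographically) and assigned a status from the thresholds: scores at
#' or above `accept` are `auto_accepted`, scores in `[review, accept)` are
#' `needs_review`, everything below is `rejected`.
#'
#' @param token normalized drug-name token
#' @param lexicon a [read_lexicon()] object
#' @param matcher scoring backend, `function(query, candidates) ->
#'   numeric`; default [levenshtein_matcher()]
#' @param accept auto-accept threshold (default 0.85)
#' @param review manual-review floor (default 0.5)
#' @param top keep at most this many candidates (default 5)
#' @return data.frame (`query`, `candidate`, `score`, `status`) sorted by
#'   descending score
#' @export
match_term <- function(token, lexicon, matcher = levenshtein_matcher,
                       accept = 0.85, review = 0.5, top = 5L) {
  nms <- names(lexicon$drugs)
  if (!length(nms)) stop2("empty lexicon")
  score <- matcher(token, nms)
  ord <- order(-score, nms)
  take <- utils::head(ord, top)
  out <- data.frame(query = token, candidate = nms[take],
                    score = score[take], stringsAsFactors = FALSE)
  out$status <- ifelse(out$score >= accept, "auto_accepted",
                       ifelse(out$score >= review, "needs_review",
                              "rejected"))
  rownames(out) <- NULL
  out
}

#' Match every medication entry of a cohort
#'
#' Tokenizes each entry with [normalize_med_text()] and keeps the top
#' candidate per token.  Unparseable entries (no tokens) are recorded with
#' status `unparseable`.
#'
#' @param meds data.frame (`subject_id`, `visit`, `raw_text`)
#' @inheritParams match_term
#' @return data.frame (`subject_id`, `raw_text`, `query`, `candidate`,
#'   `score`, `status`)
#' @export
match_meds <- function(meds, lexicon, matcher = levenshtein_matcher,
                       accept = 0.85, review = 0.5) {
  stopifnot(all(c("subject_id", "raw_text") %in% names(meds)))
  rows <- list()
  for (i in seq_len(nrow(meds))) {
    toks <- normalize_med_text(meds$raw_text[i])
    if (!length(toks)) {
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = meds$subject_id[i],
                   raw_text = meds$raw_text[i], query = "",
                   candidate = NA_character_, score = NA_real_,
                   status = "unparseable", stringsAsFactors = FALSE)
      next
    }
    for (tok in toks) {
      cand <- match_term(tok, lexicon, matcher, accept, review)[1, ]
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = meds$subject_id[i],
                   raw_text = meds$raw_text[i], query = tok,
                   candidate = cand$candidate, score = cand$score,
                   status = cand$status, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Apply manual-review decisions to matched terms
#'
#' The review table may only reference queries currently in
#' `needs_review`; each decision either accepts the query as a named
#' lexicon drug (`decision = "accept_as"`, `target` = drug name) or
#' rejects it (`decision = "reject"`).  Reviewed rows get status
#' `manually_adjusted` (with candidate replaced by the target) or
#' `rejected`.
#'
#' @param matches output of [match_meds()] (or [match_term()])
#' @param review data.frame (`query`, `decision`, `target`) or path to a
#'   CSV of the same shape; NULL / empty is a no-op
#' @return `matches` with decisions applied
#' @export
apply_review <- function(matches, review) {
  if (is.null(review)) return(matches)
  if (is.character(review)) review <- read_csv_strict(review)
  if (!nrow(review)) return(matches)
  if (!all(c("query", "decision") %in% names(review)))
    stop2("review table needs columns query, decision")
  pending <- unique(matches$query[matches$status == "needs_review"])
  unknown <- setdiff(review$query, pending)
  if (length(unknown)) {
    locked <- intersect(unknown, matches$query)
    if (length(locked))
      stop2("review of item(s) not awaiting review: ",
            paste(locked, collapse = ", "))
    stop2("review row(s) reference unknown query: ",
          paste(unknown, collapse = ", "))
  }
  for (i in seq_len(nrow(review))) {
    hit <- matches$query == review$query[i] &
      matches$status == "needs_review"
    if (review$decision[i] == "accept_as") {
      tgt <- review$target[i]
      if (is.na(tgt) || !nzchar(tgt))
        stop2("accept_as decision without target for ", review$query[i])
      matches$candidate[hit] <- tgt
      matches$status[hit] <- "manually_adjusted"
    } else if (review$decision[i] == "reject") {
      matches$status[hit] <- "rejected"
    } else stop2("unknown review decision: ", review$decision[i])
  }
  matches
}

#' Roll accepted matches up to a subject x drug-class Boolean matrix
#'
#' Accepted candidates (`auto_accepted` or `manually_adjusted`) are mapped
#' to their ingredients and then to ingredient classes; a cell is TRUE iff
#' some accepted entry of the subject carries that class.  Classes outside
#' `class_list` are ignored; subjects with no accepted entry give all-FALSE
#' rows.
#'
#' @param matches matched (and reviewed) term table
#' @param lexicon a [read_lexicon()] object
#' @param class_list character vector of class names defining the columns
#'   (default: the bundled class set)
#' @param subjects optional roster of subject ids for the rows (default:
#'   subjects present in `matches`)
#' @return data.frame: `subject_id` plus one logical column per class
#' @export
map_to_classes <- function(matches, lexicon,
                           class_list = default_drug_classes()$class,
                           subjects = NULL) {
  if (!length(class_list)) stop2("class_list must be non-empty")
  subjects <- subjects %||% unique(matches$subject_id)
  mat <- matrix(FALSE, length(subjects), length(class_list),
                dimnames = list(subjects, class_list))
  acc <- matches[matches$status %in% c("auto_accepted", "manually_adjusted"),
                 , drop = FALSE]
  for (i in seq_len(nrow(acc))) {
    drug <- acc$candidate[i]
    ings <- lexicon$drugs[[drug]]
    if (is.null(ings)) stop2("accepted drug not in lexicon: ", drug)
    cls <- unique(unlist(lapply(ings, function(ing)
      vapply(lexicon$ingredients[[ing]], `[[`, "", "class"))))
    cls <- intersect(cls, class_list)
    if (acc$subject_id[i] %in% subjects)
      mat[acc$subject_id[i], cls] <- TRUE
  }
  out <- data.frame(subject_id = subjects, stringsAsFactors = FALSE,
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(mat, check.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Full medication classification pipeline
#'
#' Normalize, match, apply review decisions, map to classes.  Deterministic
#' given lexicon, thresholds and review file.
#'
#' @param meds medication table (`subject_id`, `visit`, `raw_text`) or a
#'   CSV path
#' @inheritParams match_meds
#' @inheritParams apply_review
#' @inheritParams map_to_classes
#' @return list with `classes` (the Boolean matrix data.frame) and
#'   `matches` (the per-token match table after review)
#' @export
classify_medications <- function(meds, lexicon = read_lexicon(),
                                 review = NULL,
                                 class_list = default_drug_classes()$class,
                                 matcher = levenshtein_matcher,
                                 accept = 0.85, review_floor = 0.5) {
  if (is.character(meds)) meds <- read_csv_strict(meds)
  matches <- match_meds(meds, lexicon, matcher, accept, review_floor)
  matches <- apply_review(matches, review)
  classes <- map_to_classes(matches, lexicon, class_list,
                            subjects = unique(meds$subject_id))
  list(classes = classes, matches = matches)
}
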