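#' Default keyword lists for BUP-XR cessation screening
#'
#' `sublocade_variants()` returns the 20 explicit search strings used to
#' identify mentions of extended-release buprenorphine (brand Sublocade):
#' the brand name plus 19 misspellings, every one within Levenshtein
#' distance 1 of `"sublocade"`. `cessation_keywords()` returns the eight
#' treatment-cessation keywords.
#'
#' @return A character vector.
#' @export
sublocade_variants <- function() {
  c("sublocade", "subloccade", "sublacade", "sulocade", "subblocade",
    "sublucade", "sublockade", "sublocate", "subloocade", "sublcocade",
    "sublocode", "suublocade", "subloclade", "sublicade", "sublocades",
    "subclocade", "sublocane", "sublocadr", "sublocase", "subocade")
}

#' @rdname sublocade_variants
#' @export
cessation_keywords <- function() {
  c("taper", "stop", "final", "quit", "last", "reduce", "decrease",
    "discontinue")
}

#' Screening criteria for corpus inclusion
#'
#' Bundles the study's inclusion rules: the seed drug term and its explicit
#' spelling variants (or a generative edit-distance rule), the cessation
#' keywords, the subreddit context set, and the date window. Validates that
#' every explicit variant is within `max_distance` of the seed term under
#' case-insensitive Levenshtein distance.
#'
#' @param seed_term Canonical drug term (default `"sublocade"`).
#' @param max_distance Maximum edit distance for fuzzy matching (default 1).
#' @param explicit_variants Ordered character vector of search strings
#'   (default [sublocade_variants()]).
#' @param cessation_keywords Cessation keyword list (default
#'   [cessation_keywords()]).
#' @param context_subreddits Lowercased subreddit names whose records are
#'   included regardless of keywords (default `"sublocade"`).
#' @param window_start,window_end Inclusive date window (defaults 2018-03-01
#'   and 2022-08-31, the period of US commercial availability covered).
#' @param match_mode `"substring_list"` (default: any explicit variant as a
#'   case-insensitive substring) or `"generative_token"` (any token within
#'   `max_distance` of `seed_term`).
#' @return An object of class `screening_criteria`.
#' @export
screening_criteria <- function(seed_term = "sublocade",
                               max_distance = 1L,
                               explicit_variants = sublocade_variants(),
                               cessation_keywords = soclisten::cessation_keywords(),
                               context_subreddits = "sublocade",
                               window_start = as.Date("2018-03-01"),
                               window_end = as.Date("2022-08-31"),
                               match_mode = c("substring_list", "generative_token")) {
  match_mode <- arg_match(match_mode)
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  if (!length(explicit_variants)) abort("explicit_variants must be non-empty")
  if (!length(cessation_keywords)) abort("cessation_keywords must be non-empty")
  if (!length(context_subreddits)) abort("context_subreddits must be non-empty")
  if (window_start > window_end) abort("window_start must not be after window_end")
  d <- edit_distance(seed_term, explicit_variants, case_insensitive = TRUE)
  if (any(d > max_distance)) {
    abort(paste0("explicit variant(s) beyond max_distance of seed term: ",
                 paste(explicit_variants[d > max_distance], collapse = ", ")))
  }
  structure(
    list(
      seed_term = tolower(seed_term),
      max_distance = as.integer(max_distance),
      explicit_variants = tolower(explicit_variants),
      cessation_keywords = tolower(cessation_keywords),
      context_subreddits = tolower(context_subreddits),
      window_start = window_start,
      window_end = window_end,
      match_mode = match_mode
    ),
    class = "screening_criteria"
  )
}

#' @export
print.screening_criteria <- function(x, ...) {
  cat("<screening_criteria>\n")
  cat("  seed term:        ", x$seed_term, " (max distance ", x$max_distance, ")\n", sep = "")
  cat("  explicit variants:", length(x$explicit_variants), "strings\n")
  cat("  cessation kws:    ", paste(x$cessation_keywords, collapse = ", "), "\n")
  cat("  context subs:     ", paste(x$context_subreddits, collapse = ", "), "\n")
  cat("  window:           ", format(x$window_start), "..", format(x$window_end), "\n")
  cat("  match mode:       ", x$match_mode, "\n")
  invisible(x)
}

#' Levenshtein edit distance
#'
#' Unit-cost insertions, deletions and substitutions; symmetric; zero iff the
#' strings are equal (after ASCII case folding when `case_insensitive`).
#' Vectorized with the usual length-1 recycling.
#'
#' @param a,b Character vectors (equal length, or either of length 1).
#' @param case_insensitive Fold ASCII case before comparing (default `TRUE`,
#'   matching the case-insensitive inclusion criteria).
#' @return Integer vector of distances.
#' @examples
#' edit_distance("sublocade", "subocade")  # 1
#' edit_distance("kitten", "sitting")      # 3
#' @export
edit_distance <- function(a, b, case_insensitive = TRUE) {
  .levenshtein(as.character(a), as.character(b), isTRUE(case_insensitive))
}

#' Enumerate all strings within an edit distance of a term
#'
#' Generates exactly the set of strings over `alphabet` whose Levenshtein
#' distance from `term` is at most `max_distance` (the term itself included),
#' by iterated single-edit expansion. A size guard refuses runaway
#' enumerations.
#'
#' @param term Seed string.
#' @param max_distance Non-negative integer.
#' @param alphabet Character vector of single characters (default `letters`).
#' @param cap Maximum number of candidate strings to hold (default `1e6`).
#' @return Sorted character vector of variants.
#' @export
enumerate_variants <- function(term, max_distance = 1L, alphabet = letters,
                               cap = 1e6) {
  stopifnot(max_distance >= 0, length(alphabet) > 0)
  term <- tolower(term)
  alphabet <- unique(tolower(alphabet))
  current <- term
  all <- term
  for (d in seq_len(max_distance)) {
    nxt <- unique(unlist(lapply(current, single_edits, alphabet = alphabet)))
    all <- unique(c(all, nxt))
    if (length(all) > cap) {
      abort(sprintf("enumerate_variants: variant set exceeds cap of %g", cap))
    }
    current <- nxt
  }
  sort(all)
}

# all strings at edit distance exactly <= 1 from s (one edit applied)
single_edits <- function(s, alphabet) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  dels <- if (n > 0) vapply(seq_len(n), function(i)
    paste(chars[-i], collapse = ""), character(1)) else character(0)
  subs <- unlist(lapply(seq_len(n), function(i) {
    repl <- setdiff(alphabet, chars[i])
    vapply(repl, function(a) {
      tmp <- chars; tmp[i] <- a; paste(tmp, collapse = "")
    }, character(1))
  }))
  ins <- unlist(lapply(seq_len(n + 1), function(i) {
    vapply(alphabet, function(a) {
      paste(c(head(chars, i - 1), a, chars[seq_len(n) >= i]), collapse = "")
    }, character(1))
  }))
  unique(c(dels, subs, ins))
}

# locate every case-insensitive occurrence of each keyword in each text;
# returns a list (one per text) of tibbles (keyword, position)
locate_keywords <- function(text, keywords) {
  text <- as.character(text)
  hits <- vector("list", length(text))
  for (i in seq_along(hits)) hits[[i]] <- list()
  for (kw in keywords) {
    loc <- stringr::str_locate_all(text, stringr::fixed(kw, ignore_case = TRUE))
    for (i in seq_along(loc)) {
      if (nrow(loc[[i]])) {
        hits[[i]][[length(hits[[i]]) + 1]] <-
          tibble(keyword = kw, position = as.integer(loc[[i]][, "start"]))
      }
    }
  }
  lapply(hits, function(h) {
    if (length(h)) arrange(bind_rows(h), .data$position, .data$keyword)
    else tibble(keyword = character(0), position = integer(0))
  })
}

#' Match drug-term keywords in free text
#'
#' In `substring_list` mode a text matches iff any explicit variant occurs
#' case-insensitively as a substring (the study's operationalization of the
#' distance-1 rule: Table-style fixed list, "contains" semantics). In
#' `generative_token` mode a text matches iff any
#' whitespace/punctuation-delimited token is within `max_distance` of the
#' seed term.
#'
#' @param text Character vector.
#' @param criteria A [screening_criteria()].
#' @return Tibble with one row per text: `matched` (logical) and `matches`
#'   (list of tibbles `keyword`, `position`; in token mode `position` is the
#'   token index).
#' @export
match_term <- function(text, criteria) {
  stopifnot(inherits(criteria, "screening_criteria"))
  if (criteria$match_mode == "substring_list") {
    m <- locate_keywords(text, criteria$explicit_variants)
  } else {
    m <- lapply(as.character(text), function(t) {
      toks <- strsplit(tolower(t), "[^[:alnum:]]+")[[1]]
      toks <- toks[nzchar(toks)]
      if (!length(toks)) {
        return(tibble(keyword = character(0), position = integer(0)))
      }
      d <- edit_distance(toks, criteria$seed_term)
      keep <- which(d <= criteria$max_distance)
      tibble(keyword = toks[keep], position = keep)
    })
  }
  tibble(matched = vapply(m, nrow, integer(1)) > 0L, matches = m)
}

#' Match cessation keywords in free text
#'
#' Substring semantics identical to [match_term()]'s list mode, over the
#' cessation keyword list. `mode = "token"` is a stricter whole-word variant
#' (keyword must equal a delimited token), offered because substring matching
#' has a known false-positive surface (e.g. "last" inside "at last").
#'
#' @inheritParams match_term
#' @param mode `"substring"` (default, the study rule) or `"token"`.
#' @return Tibble with `matched` and `matches` as in [match_term()].
#' @export
match_cessation <- function(text, criteria, mode = c("substring", "token")) {
  stopifnot(inherits(criteria, "screening_criteria"))
  mode <- arg_match(mode)
  if (mode == "substring") {
    m <- locate_keywords(text, criteria$cessation_keywords)
  } else {
    m <- lapply(as.character(text), function(t) {
      toks <- strsplit(tolower(t), "[^[:alnum:]]+")[[1]]
      toks <- toks[nzchar(toks)]
      keep <- which(toks %in% criteria$cessation_keywords)
      tibble(keyword = toks[keep], position = keep)
    })
  }
  tibble(matched = vapply(m, nrow, integer(1)) > 0L, matches = m)
}

#' Subreddit context and date-window predicates
#'
#' `match_context()` is true iff the record's (lowercased) subreddit is in
#' the context set. `within_window()` is true iff the date lies in the
#' inclusive study window.
#'
#' @param subreddit Character vector of lowercased subreddit names.
#' @param created_date A `Date` vector.
#' @param criteria A [screening_criteria()].
#' @return Logical vector.
#' @export
match_context <- function(subreddit, criteria) {
  stopifnot(inherits(criteria, "screening_criteria"))
  tolower(subreddit) %in% criteria$context_subreddits
}

#' @rdname match_context
#' @export
within_window <- function(created_date, criteria) {
  stopifnot(inherits(criteria, "screening_criteria"))
  created_date <- as.Date(created_date)
  created_date >= criteria$window_start & created_date <= criteria$window_end
}

#' Screen a normalized corpus through the study's inclusion gates
#'
#' Applies the inclusion criteria in the study's fixed order:
#' \enumerate{
#'   \item \strong{referent gate} — keep records matching the drug-term
#'     keywords OR created in a context subreddit (parallel criteria);
#'   \item \strong{deduplication} — keep the first occurrence of each
#'     `record_id`;
#'   \item \strong{cessation gate} — keep records matching a cessation
#'     keyword;
#'   \item \strong{date window} — keep records inside the inclusive window.
#' }
#' Each retained record carries the labels of the rules that admitted it
#' (`term_keyword`, `subreddit_context`, `cessation_keyword`) plus the
#' matched strings.
#'
#' @param records Tibble of normalized records ([normalize_records()]).
#' @param criteria A [screening_criteria()].
#' @param cessation_mode Passed to [match_cessation()].
#' @return An object of class `screened_corpus`: list with `records` (the
#'   retained tibble, with `match_criteria` and `matched_strings` columns)
#'   and `attrition` (per-stage counts: `stage`, `n_in`, `n_out`,
#'   `n_removed`). [tidy()] returns the attrition table.
#' @export
screen_corpus <- function(records, criteria,
                          cessation_mode = c("substring", "token")) {
  stopifnot(inherits(criteria, "screening_criteria"))
  cessation_mode <- arg_match(cessation_mode)
  stages <- c("referent_gate", "deduplication", "cessation_gate", "date_window")
  if (nrow(records) == 0) {
    att <- tibble(stage = stages, n_in = 0L, n_out = 0L, n_removed = 0L)
    out <- records
    out$match_criteria <- list()
    out$matched_strings <- list()
    ids0 <- list(term_keyword = character(0), subreddit_context = character(0),
                 referent = character(0), cessation = character(0),
                 window = character(0))
    return(structure(list(records = out, attrition = att, criteria = criteria,
                          stage_ids = ids0),
                     class = "screened_corpus"))
  }

  # stage 1: parallel referent criteria (term keyword OR subreddit context)
  term <- match_term(records$text, criteria)
  ctx <- match_context(records$subreddit, criteria)
  keep1 <- term$matched | ctx
  s1 <- records[keep1, , drop = FALSE]
  s1$match_criteria <- Map(function(t, c) {
    c(if (t) "term_keyword", if (c) "subreddit_context")
  }, term$matched[keep1], ctx[keep1])
  s1$matched_strings <- lapply(term$matches[keep1], function(m) unique(m$keyword))

  # stage 2: deduplicate on the obfuscated record id, first occurrence kept
  s2 <- distinct(s1, .data$record_id, .keep_all = TRUE)

  # stage 3: cessation keyword gate
  cess <- match_cessation(s2$text, criteria, mode = cessation_mode)
  s3 <- s2[cess$matched, , drop = FALSE]
  s3$match_criteria <- Map(c, s3$match_criteria, "cessation_keyword")
  s3$matched_strings <- Map(function(a, m) unique(c(a, m$keyword)),
                            s3$matched_strings,
                            cess$matches[cess$matched])

  # stage 4: inclusive date window
  keep4 <- within_window(s3$created_date, criteria)
  s4 <- s3[keep4, , drop = FALSE]

  n_in <- c(nrow(records), nrow(s1), nrow(s2), nrow(s3))
  n_out <- c(nrow(s1), nrow(s2), nrow(s3), nrow(s4))
  att <- tibble(stage = stages, n_in = as.integer(n_in),
                n_out = as.integer(n_out),
                n_removed = as.integer(n_in - n_out))
  # unique-id membership per gate, for recovery evaluation against truth
  stage_ids <- list(
    term_keyword = unique(records$record_id[term$matched]),
    subreddit_context = unique(records$record_id[ctx]),
    referent = unique(s1$record_id),
    cessation = s3$record_id,
    window = s4$record_id
  )
  structure(list(records = s4, attrition = att, criteria = criteria,
                 stage_ids = stage_ids),
            class = "screened_corpus")
}

#' @export
print.screened_corpus <- function(x, ...) {
  cat("<screened_corpus> ", nrow(x$records), " record(s) retained\n", sep = "")
  print(as.data.frame(x$attrition), row.names = FALSE)
  invisible(x)
}

#' @rdname screen_corpus
#' @param x A `screened_corpus`.
#' @param ... Unused.
#' @export
tidy.screened_corpus <- function(x, ...) {
  x$attrition
}
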