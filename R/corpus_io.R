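#' Read Reddit-style records from a Pushshift-dialect JSON Lines file
#'
#' Each line is one JSON object with the Pushshift field names: `id`,
#' `author`, `created_utc`, `subreddit`, and either `body` (comments) or
#' `title`/`selftext` (submissions). Malformed lines are skipped and counted,
#' never fatal; a file with zero parseable lines is an error.
#'
#' @param path Path to a JSON Lines file.
#' @param dialect Input dialect; only `"pushshift_jsonl"` is supported.
#' @return A tibble of raw records with columns `id`, `author`, `created_utc`,
#'   `subreddit`, `kind` (`"submission"` or `"comment"`), `title`, `selftext`,
#'   `body`. The number of skipped lines is attached as attribute
#'   `n_malformed`.
#' @export
read_records <- function(path, dialect = "pushshift_jsonl") {
  dialect <- arg_match(dialect, "pushshift_jsonl")
  if (!file.exists(path)) {
    abort(paste0("cannot read records: no such file: ", path))
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  parsed <- lapply(lines, function(l) {
    tryCatch(jsonlite::fromJSON(l, simplifyVector = TRUE), error = function(e) NULL)
  })
  bad <- vapply(parsed, is.null, logical(1))
  if (all(bad) || length(parsed) == 0) {
    abort(paste0("empty corpus: no parseable JSON lines in ", path))
  }
  if (any(bad)) {
    inform(sprintf("read_records: skipped %d malformed line(s)", sum(bad)))
  }
  recs <- parsed[!bad]
  chr1 <- function(x, f) {
    v <- x[[f]]
    if (is.null(v) || length(v) == 0) NA_character_ else as.character(v[[1]])
  }
  out <- tibble(
    id          = vapply(recs, chr1, character(1), f = "id"),
    author      = vapply(recs, chr1, character(1), f = "author"),
    created_utc = vapply(recs, function(x) {
      v <- x[["created_utc"]]
      if (is.null(v)) NA_real_ else as.numeric(v[[1]])
    }, numeric(1)),
    subreddit   = vapply(recs, chr1, character(1), f = "subreddit"),
    title       = vapply(recs, chr1, character(1), f = "title"),
    selftext    = vapply(recs, chr1, character(1), f = "selftext"),
    body        = vapply(recs, chr1, character(1), f = "body")
  )
  out <- mutate(out, kind = ifelse(!is.na(.data$body), "comment", "submission"),
                .after = "subreddit")
  attr(out, "n_malformed") <- sum(bad)
  out
}

#' Write raw records as Pushshift-dialect JSON Lines
#'
#' Inverse of [read_records()]: `NA` fields are dropped per line, so comments
#' carry `body` and submissions carry `title`/`selftext`, as in the original
#' dialect. Round-trips record count and all field values.
#'
#' @param records Tibble of raw records (as from [read_records()] or
#'   [generate_corpus()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  fields <- c("id", "author", "created_utc", "subreddit", "title", "selftext", "body")
  fields <- intersect(fields, names(records))
  lines <- vapply(seq_len(nrow(records)), function(i) {
    row <- as.list(records[i, fields])
    row <- row[!vapply(row, function(v) is.na(v), logical(1))]
    as.character(jsonlite::toJSON(row, auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Normalize raw records into the analysis schema
#'
#' Builds one unified text field per record (a comment's `body`; a
#' submission's `title` and `selftext` joined by a single newline, missing
#' parts treated as empty), lowercases the subreddit, converts the epoch
#' timestamp to a UTC calendar date, and replaces the platform `id`/`author`
#' with salted one-way tokens (see [obfuscate()]).
#'
#' @param records Tibble of raw records.
#' @param config An [obfuscation_config()].
#' @return Tibble with columns `record_id`, `author_id`, `created_utc`,
#'   `created_date`, `subreddit`, `kind`, `text`, `empty_text`.
#' @export
normalize_records <- function(records, config) {
  stopifnot(inherits(config, "obfuscation_config"))
  blank <- function(x) ifelse(is.na(x), "", x)
  if (!"kind" %in% names(records)) {
    records$kind <- ifelse(!is.na(records$body), "comment", "submission")
  }
  text <- ifelse(
    records$kind == "comment",
    blank(records$body),
    # submissions: title and selftext both searched; newline keeps per-field
    # substring matches intact
    paste(blank(records$title), blank(records$selftext), sep = "\n")
  )
  # a submission with only a title should not carry a trailing newline
  text <- sub("^\n", "", sub("\n$", "", text))
  tibble(
    record_id    = obfuscate(records$id, config),
    author_id    = obfuscate(records$author, config),
    created_utc  = records$created_utc,
    created_date = as.Date(as.POSIXct(records$created_utc,
                                      origin = "1970-01-01", tz = "UTC")),
    subreddit    = tolower(records$subreddit),
    kind         = records$kind,
    text         = text,
    empty_text   = !nzchar(trimws(text))
  )
}

#' Write or read normalized records
#'
#' Normalized records are stored as JSON Lines (dates ISO 8601) or CSV with
#' identical columns.
#'
#' @param records Tibble of normalized records.
#' @param path Output path.
#' @return `path` (writers, invisibly) or a tibble (reader).
#' @export
write_normalized <- function(records, path) {
  df <- mutate(records, created_date = as.character(.data$created_date))
  cols <- setdiff(names(df), "match_criteria")
  has_mc <- "match_criteria" %in% names(df)
  lines <- vapply(seq_len(nrow(df)), function(i) {
    row <- as.list(df[i, cols])
    if (has_mc) row$match_criteria <- df$match_criteria[[i]]
    as.character(jsonlite::toJSON(row, auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_normalized
#' @export
read_normalized <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  out <- tibble(
    record_id    = vapply(recs, function(x) x$record_id, character(1)),
    author_id    = vapply(recs, function(x) x$author_id, character(1)),
    created_utc  = vapply(recs, function(x) as.numeric(x$created_utc), numeric(1)),
    created_date = as.Date(vapply(recs, function(x) x$created_date, character(1))),
    subreddit    = vapply(recs, function(x) x$subreddit, character(1)),
    kind         = vapply(recs, function(x) x$kind, character(1)),
    text         = vapply(recs, function(x) x$text, character(1)),
    empty_text   = vapply(recs, function(x) isTRUE(x$empty_text), logical(1))
  )
  if (any(vapply(recs, function(x) !is.null(x$match_criteria), logical(1)))) {
    out$match_criteria <- lapply(recs, function(x) {
      mc <- x$match_criteria
      if (is.null(mc)) character(0) else as.character(mc)
    })
  }
  out
}

#' @rdname write_normalized
#' @export
write_normalized_csv <- function(records, path) {
  df <- records
  if ("match_criteria" %in% names(df)) {
    df$match_criteria <- vapply(df$match_criteria, paste, character(1), collapse = ";")
  }
  readr::write_csv(df, path)
  invisible(path)
}
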