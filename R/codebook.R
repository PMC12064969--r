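#' The annotation codebook schema
#'
#' `codebook_fields()` is the manifest of the dataset schema used for manual
#' coding: every field of the codebook, its snake_case column name, its type,
#' and whether it lives on the record side (identifiers, text, provenance) or
#' the annotation side (coded constructs). `cessation_timing`
#' (retrospective vs planned cessation) is carried in addition to the listed
#' construct columns because the study reports that split.
#'
#' @return Tibble with columns `field_name`, `column`, `type`, `where`.
#' @export
codebook_fields <- function() {
  tibble::tribble(
    ~field_name,                          ~column,                    ~type,      ~where,
    "ID",                                 "record_id",                "text",     "record",
    "Text",                               "text",                     "text",     "record",
    "Author ID",                          "author_id",                "text",     "record",
    "Created date",                       "created_date",             "date",     "record",
    "Match criteria",                     "match_criteria",           "text",     "record",
    "Notes",                              "notes",                    "text",     "annotation",
    "Sublocade",                          "sublocade",                "binary",   "annotation",
    "Any cessation",                      "any_cessation",            "binary",   "annotation",
    "Intentional cessation",              "intentional_cessation",    "binary",   "annotation",
    "Circumstantial cessation",           "circumstantial_cessation", "binary",   "annotation",
    "Within-course withdrawal",           "within_course_withdrawal", "binary",   "annotation",
    "Postcourse withdrawal",              "postcourse_withdrawal",    "binary",   "annotation",
    "Opioid craving",                     "opioid_craving",           "binary",   "annotation",
    "Final dosage",                       "final_dosage",             "integer",  "annotation",
    "Duration of MOUD treatment",         "duration_moud",            "integer",  "annotation",
    "Duration of buprenorphine treatment","duration_buprenorphine",   "integer",  "annotation",
    "Duration of Sublocade treatment",    "duration_sublocade",       "integer",  "annotation",
    "Course of treatment",                "course_of_treatment",      "array",    "annotation",
    "Number of doses",                    "number_of_doses",          "integer",  "annotation",
    "Prior MOUD",                         "prior_moud",               "text",     "annotation",
    "Subsequent MOUD",                    "subsequent_moud",          "text",     "annotation",
    "Concurrent MOUD",                    "concurrent_moud",          "text",     "annotation",
    "Subsequent NMOU",                    "subsequent_nmou",          "text",     "annotation",
    "Concurrent NMOU",                    "concurrent_nmou",          "text",     "annotation"
  )
}

annotation_columns <- function() {
  c(filter(codebook_fields(), .data$where == "annotation")$column,
    "cessation_timing")
}

binary_columns <- function() {
  filter(codebook_fields(), .data$type == "binary")$column
}

#' An empty, correctly-typed annotation tibble
#'
#' @param n Number of blank rows (default 0).
#' @return Tibble with one column per annotation field (binaries `NA_integer_`,
#'   `course_of_treatment` a list column of integer vectors).
#' @export
empty_annotations <- function(n = 0) {
  tibble(
    record_id = character(n),
    sublocade = NA_integer_[rep(1, n)],
    any_cessation = NA_integer_[rep(1, n)],
    intentional_cessation = NA_integer_[rep(1, n)],
    circumstantial_cessation = NA_integer_[rep(1, n)],
    within_course_withdrawal = NA_integer_[rep(1, n)],
    postcourse_withdrawal = NA_integer_[rep(1, n)],
    opioid_craving = NA_integer_[rep(1, n)],
    final_dosage = NA_integer_[rep(1, n)],
    duration_moud = NA_integer_[rep(1, n)],
    duration_buprenorphine = NA_integer_[rep(1, n)],
    duration_sublocade = NA_integer_[rep(1, n)],
    course_of_treatment = rep(list(integer(0)), n),
    number_of_doses = NA_integer_[rep(1, n)],
    prior_moud = NA_character_[rep(1, n)],
    subsequent_moud = NA_character_[rep(1, n)],
    concurrent_moud = NA_character_[rep(1, n)],
    subsequent_nmou = NA_character_[rep(1, n)],
    concurrent_nmou = NA_character_[rep(1, n)],
    notes = NA_character_[rep(1, n)],
    cessation_timing = NA_character_[rep(1, n)]
  )
}

#' Parse a dose-sequence string
#'
#' Courses of treatment are recorded as comma-separated milligram doses,
#' e.g. `"100, 300, 300, 100"`. Whitespace is tolerated; the empty string is
#' an empty course; a non-numeric token is an error naming the token.
#'
#' @param text A single string.
#' @return Integer vector of doses, in order.
#' @examples
#' parse_course("100, 300, 300, 100")
#' @export
parse_course <- function(text) {
  if (length(text) != 1) abort("parse_course() takes a single string")
  if (is.na(text) || !nzchar(trimws(text))) return(integer(0))
  toks <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  bad <- !grepl("^[0-9]+$", toks)
  if (any(bad)) {
    abort(paste0("non-numeric dose token(s) in course: ",
                 paste(unique(toks[bad]), collapse = ", ")))
  }
  as.integer(toks)
}

#' @rdname parse_course
#' @param course Integer vector of doses.
#' @export
format_course <- function(course) {
  if (!length(course)) return("")
  paste(course, collapse = ", ")
}

#' Read or write annotation tables
#'
#' Annotations travel as CSV with exactly the codebook's snake_case column
#' names, one row per record; `course_of_treatment` is serialized with
#' [format_course()].
#'
#' @param annotations Annotation tibble.
#' @param path CSV path.
#' @return `path` (writer, invisibly) or an annotation tibble (reader).
#' @export
write_annotations <- function(annotations, path) {
  df <- annotations
  df$course_of_treatment <- vapply(df$course_of_treatment, format_course,
                                   character(1))
  readr::write_csv(df, path, na = "")
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      record_id = readr::col_character(),
      course_of_treatment = readr::col_character(),
      prior_moud = readr::col_character(),
      subsequent_moud = readr::col_character(),
      concurrent_moud = readr::col_character(),
      subsequent_nmou = readr::col_character(),
      concurrent_nmou = readr::col_character(),
      notes = readr::col_character(),
      cessation_timing = readr::col_character(),
      .default = readr::col_integer()
    ),
    na = c("", "NA")
  )
  missing_cols <- setdiff(c("record_id", annotation_columns()), names(df))
  if (length(missing_cols)) {
    abort(paste0("annotation file lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  df$course_of_treatment <- lapply(
    ifelse(is.na(df$course_of_treatment), "", df$course_of_treatment),
    parse_course
  )
  as_tibble(df)
}

# single-annotation rule checks; returns tibble(rule, severity, message)
check_annotation_row <- function(a) {
  out <- list()
  note <- function(rule, severity, message) {
    out[[length(out) + 1]] <<- tibble(rule = rule, severity = severity,
                                      message = message)
  }
  for (col in binary_columns()) {
    v <- a[[col]]
    if (!is.na(v) && !(v %in% c(0L, 1L))) {
      note("binary_domain", "error", paste0(col, " must be 0 or 1, got ", v))
    }
  }
  bin <- function(col) isTRUE(a[[col]] == 1L)
  if ((bin("intentional_cessation") || bin("circumstantial_cessation")) &&
      !bin("any_cessation")) {
    note("cessation_implies_any", "error",
         "intentional/circumstantial cessation coded without any_cessation")
  }
  if ((bin("any_cessation") || bin("within_course_withdrawal") ||
       bin("postcourse_withdrawal")) && !bin("sublocade")) {
    note("construct_implies_referent", "error",
         "cessation/withdrawal construct coded without a Sublocade referent")
  }
  course <- a$course_of_treatment[[1]]
  if (length(course) && !is.na(a$number_of_doses) &&
      length(course) != a$number_of_doses) {
    note("course_length", "error",
         sprintf("course has %d dose(s) but number_of_doses is %d",
                 length(course), a$number_of_doses))
  }
  if (length(course) && !is.na(a$final_dosage) &&
      a$final_dosage != course[length(course)]) {
    note("final_dose_consistent", "error",
         sprintf("final_dosage %d differs from last course dose %d",
                 a$final_dosage, course[length(course)]))
  }
  doses <- c(course, if (!is.na(a$final_dosage)) a$final_dosage)
  if (length(doses)) {
    if (any(doses <= 0 | doses > 300)) {
      note("dose_range", "error",
           paste0("dose(s) outside (0, 300] mg: ",
                  paste(unique(doses[doses <= 0 | doses > 300]), collapse = ", ")))
    }
    odd <- doses[doses > 0 & doses <= 300 & doses %% 50 != 0]
    if (length(odd)) {
      note("dose_oddity", "warning",
           paste0("unusual dose value(s) (not a multiple of 50 mg): ",
                  paste(unique(odd), collapse = ", ")))
    }
  }
  durs <- c(moud = a$duration_moud, bup = a$duration_buprenorphine,
            sub = a$duration_sublocade)
  if (any(!is.na(durs) & durs < 0)) {
    note("duration_nonnegative", "error", "negative treatment duration")
  }
  if (!is.na(a$duration_sublocade) && !is.na(a$duration_buprenorphine) &&
      a$duration_sublocade > a$duration_buprenorphine) {
    note("duration_ordering", "error",
         "duration_sublocade exceeds duration_buprenorphine")
  }
  if (!is.na(a$duration_buprenorphine) && !is.na(a$duration_moud) &&
      a$duration_buprenorphine > a$duration_moud) {
    note("duration_ordering", "error",
         "duration_buprenorphine exceeds duration_moud")
  }
  if (!is.na(a$cessation_timing)) {
    if (!a$cessation_timing %in% c("retrospective", "planned")) {
      note("timing_domain", "error",
           paste0("cessation_timing must be retrospective or planned, got ",
                  a$cessation_timing))
    } else if (!bin("any_cessation")) {
      note("timing_implies_cessation", "error",
           "cessation_timing coded without any_cessation")
    }
  }
  if (length(out)) bind_rows(out) else
    tibble(rule = character(0), severity = character(0), message = character(0))
}

#' Validate annotations against the codebook invariants
#'
#' Checks every logical invariant of the coding scheme: binary domains,
#' construct implications (a coded cessation implies a coded drug referent),
#' course/dose-count/final-dose consistency, dose ranges (errors outside
#' (0, 300] mg, warnings for implausible in-range values), duration ordering
#' (Sublocade ≤ buprenorphine ≤ any-MOUD), and the timing enum. Violations
#' are data, not exceptions: each yields one report row.
#'
#' @param annotations Annotation tibble.
#' @return Tibble with columns `record_id`, `rule`, `severity`, `message`;
#'   zero rows iff every annotation is valid.
#' @export
validate_annotations <- function(annotations) {
  reports <- lapply(seq_len(nrow(annotations)), function(i) {
    rep <- check_annotation_row(annotations[i, ])
    if (nrow(rep)) rep$record_id <- annotations$record_id[i]
    rep
  })
  out <- bind_rows(reports)
  if (!nrow(out)) {
    return(tibble(record_id = character(0), rule = character(0),
                  severity = character(0), message = character(0)))
  }
  select(out, "record_id", "rule", "severity", "message")
}

#' Join annotations to normalized records
#'
#' Left join on `record_id`. Unannotated records are flagged
#' (`annotated = FALSE`); annotations whose id has no record are orphans,
#' reported via the `orphans` attribute; two annotations for one record are
#' an error.
#'
#' @param records Tibble of normalized/screened records.
#' @param annotations Annotation tibble.
#' @return The joined tibble with an `annotated` flag; attribute `orphans`
#'   holds orphan record ids.
#' @export
join_annotations <- function(records, annotations) {
  dup <- annotations$record_id[duplicated(annotations$record_id)]
  if (length(dup)) {
    abort(paste0("duplicate annotation(s) for record id(s): ",
                 paste(unique(dup), collapse = ", ")))
  }
  orphans <- setdiff(annotations$record_id, records$record_id)
  if (length(orphans)) {
    inform(sprintf("join_annotations: %d orphan annotation(s) have no record",
                   length(orphans)))
  }
  out <- left_join(records, annotations, by = "record_id",
                   suffix = c("", ".annotation"))
  out$annotated <- records$record_id %in% annotations$record_id
  attr(out, "orphans") <- orphans
  out
}
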