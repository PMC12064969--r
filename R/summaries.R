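#' Per-author activity statistics
#'
#' Counts records per obfuscated author id and summarises: number of unique
#' authors, mean, sample SD (n − 1 denominator), minimum and maximum. With a
#' single author the SD is undefined and reported as 0 with
#' `sd_undefined = TRUE`. Author-level aggregates inherit the platform's
#' caveat that one person may hold several accounts.
#'
#' @param records Tibble with an `author_id` column.
#' @return One-row tibble `n_authors`, `mean_records`, `sd_records`,
#'   `min_records`, `max_records`, `sd_undefined`; the per-author count
#'   table is attached as attribute `per_author`.
#' @examples
#' author_stats(tibble::tibble(author_id = c("a", "a", "a", "b")))
#' @export
author_stats <- function(records) {
  if (nrow(records) == 0) {
    out <- tibble(n_authors = 0L, mean_records = NA_real_,
                  sd_records = NA_real_, min_records = NA_integer_,
                  max_records = NA_integer_, sd_undefined = TRUE)
    attr(out, "per_author") <- tibble(author_id = character(0), n = integer(0))
    return(out)
  }
  per <- count(records, .data$author_id, name = "n")
  single <- nrow(per) < 2
  out <- tibble(
    n_authors = nrow(per),
    mean_records = mean(per$n),
    sd_records = if (single) 0 else sd(per$n),
    min_records = min(per$n),
    max_records = max(per$n),
    sd_undefined = single
  )
  attr(out, "per_author") <- per
  out
}

#' Dose-sequence and final-dose distributions
#'
#' From validated annotations: the frequency of each distinct course of
#' treatment (among annotations with a non-empty course), the pooled
#' final-dose frequencies (courses contribute their last dose; final-dose-only
#' annotations contribute `final_dosage` and are counted in the final-dose
#' table but never the sequence table), the modal final dose, and
#' mean/SD/median/IQR of the number of doses. IQR is Q3 − Q1 with
#' linear-interpolation quantiles.
#'
#' @param annotations Annotation tibble.
#' @return Object of class `dose_distributions`: list with
#'   `sequence_dist` (tibble `course`, `n`), `final_dose_dist` (tibble
#'   `dose`, `n`), `final_dose_mode`, and `n_doses` (one-row tibble `n`,
#'   `mean`, `sd`, `median`, `iqr`).
#' @export
dose_distributions <- function(annotations) {
  has_course <- vapply(annotations$course_of_treatment, length, integer(1)) > 0
  courses <- annotations$course_of_treatment[has_course]
  seq_dist <- tibble(course = vapply(courses, format_course, character(1))) %>%
    count(.data$course, name = "n") %>%
    arrange(dplyr::desc(.data$n), .data$course)

  final_from_course <- vapply(courses, function(x) x[length(x)], integer(1))
  final_only <- annotations$final_dosage[!has_course & !is.na(annotations$final_dosage)]
  finals <- c(final_from_course, final_only)
  final_dist <- tibble(dose = as.integer(finals)) %>%
    count(.data$dose, name = "n") %>%
    arrange(dplyr::desc(.data$n), .data$dose)
  final_mode <- if (nrow(final_dist)) final_dist$dose[1] else NA_integer_

  nd <- annotations$number_of_doses
  nd <- nd[!is.na(nd)]
  n_doses <- tibble(
    n = length(nd),
    mean = if (length(nd)) mean(nd) else NA_real_,
    sd = if (length(nd) > 1) sd(nd) else NA_real_,
    median = if (length(nd)) median(nd) else NA_real_,
    iqr = if (length(nd)) unname(diff(quantile(nd, c(0.25, 0.75), type = 7)))
          else NA_real_
  )
  structure(
    list(sequence_dist = seq_dist, final_dose_dist = final_dist,
         final_dose_mode = final_mode, n_doses = n_doses),
    class = "dose_distributions"
  )
}

#' @export
print.dose_distributions <- function(x, ...) {
  cat("<dose_distributions>\n")
  cat("  distinct dose sequences:", nrow(x$sequence_dist),
      "| modal final dose:", x$final_dose_mode, "mg\n")
  cat(sprintf("  number of doses: mean %.1f, SD %.1f, median %g, IQR %g (n=%d)\n",
              x$n_doses$mean, x$n_doses$sd, x$n_doses$median, x$n_doses$iqr,
              x$n_doses$n))
  invisible(x)
}

# percent helper that tolerates zero denominators (NA) per the summary contract
pct_or_na <- function(num, den) {
  ifelse(den > 0, percentage(pmin(num, den), pmax(den, 1)), NA_real_)
}

#' Descriptive summary of the screened, sampled, annotated corpus
#'
#' Computes the study-style descriptive statistics: counts and half-up
#' percentages for the drug-referent, cessation (of the confirmed referents),
#' retrospective vs planned and withdrawal (both of the cessation records)
#' constructs, the craving count, per-author activity, the subreddit
#' distribution of the coded sample, and the dose distributions. Every
#' percentage is traceable: its numerator and denominator are carried in the
#' output.
#'
#' @param records The coded sample: a tibble of screened, sampled records.
#' @param annotations Validated annotations for (a subset of) those records.
#' @param n_total Total unique records satisfying the inclusion criteria
#'   (the pre-sampling deduplicated count); defaults to `nrow(records)`.
#' @param criteria Optional [screening_criteria()], echoed into provenance.
#' @return Object of class `corpus_summary`. Use [tidy()] for a long
#'   count/percent table, [glance()] for a one-row overview and
#'   [autoplot()] for the final-dose distribution.
#' @export
summary_report <- function(records, annotations, n_total = nrow(records),
                           criteria = NULL) {
  ann <- annotations[annotations$record_id %in% records$record_id, , drop = FALSE]
  bin_n <- function(col, data = ann) sum(data[[col]] == 1L, na.rm = TRUE)

  n_sampled <- nrow(records)
  n_sublocade <- bin_n("sublocade")
  cess <- ann[!is.na(ann$any_cessation) & ann$any_cessation == 1L, , drop = FALSE]
  n_cessation <- nrow(cess)
  n_retro <- sum(cess$cessation_timing == "retrospective", na.rm = TRUE)
  n_planned <- sum(cess$cessation_timing == "planned", na.rm = TRUE)
  n_withdrawal <- sum(
    (cess$within_course_withdrawal == 1L | cess$postcourse_withdrawal == 1L),
    na.rm = TRUE
  )
  n_craving <- bin_n("opioid_craving")

  sub_dist <- count(records, .data$subreddit, name = "n") %>%
    arrange(dplyr::desc(.data$n), .data$subreddit) %>%
    mutate(percent = pct_or_na(.data$n, n_sampled))

  structure(
    list(
      n_total = n_total,
      n_sampled = n_sampled,
      n_sublocade = n_sublocade,
      pct_sublocade = pct_or_na(n_sublocade, n_sampled),
      n_cessation = n_cessation,
      pct_cessation = pct_or_na(n_cessation, n_sublocade),
      n_retrospective = n_retro,
      pct_retrospective = pct_or_na(n_retro, n_cessation),
      n_planned = n_planned,
      pct_planned = pct_or_na(n_planned, n_cessation),
      n_withdrawal = n_withdrawal,
      pct_withdrawal = pct_or_na(n_withdrawal, n_cessation),
      n_craving = n_craving,
      authors = author_stats(records),
      subreddit_distribution = sub_dist,
      doses = dose_distributions(ann),
      n_annotated = nrow(ann),
      criteria = criteria
    ),
    class = "corpus_summary"
  )
}

#' @export
print.corpus_summary <- function(x, ...) {
  p <- function(v) ifelse(is.na(v), "NA", sprintf("%.1f%%", v))
  cat("<corpus_summary>\n")
  cat(sprintf("  %d unique records satisfied inclusion; %d sampled for coding\n",
              x$n_total, x$n_sampled))
  cat(sprintf("  drug referent confirmed: %d (%s of sample)\n",
              x$n_sublocade, p(x$pct_sublocade)))
  cat(sprintf("  cessation referenced:    %d (%s of referents)\n",
              x$n_cessation, p(x$pct_cessation)))
  cat(sprintf("    retrospective %d (%s) | planned %d (%s)\n",
              x$n_retrospective, p(x$pct_retrospective),
              x$n_planned, p(x$pct_planned)))
  cat(sprintf("  withdrawal: %d (%s of cessation) | craving: %d\n",
              x$n_withdrawal, p(x$pct_withdrawal), x$n_craving))
  a <- x$authors
  cat(sprintf("  authors: %d (range %s-%s records/account; mean %.1f, SD %.1f)\n",
              a$n_authors, a$min_records, a$max_records, a$mean_records,
              a$sd_records))
  if (nrow(x$subreddit_distribution)) {
    top <- x$subreddit_distribution[1, ]
    cat(sprintf("  top subreddit: r/%s, %d (%s)\n", top$subreddit, top$n,
                p(top$percent)))
  }
  print(x$doses)
  invisible(x)
}

#' @rdname summary_report
#' @param x A `corpus_summary`.
#' @param ... Unused.
#' @export
tidy.corpus_summary <- function(x, ...) {
  tibble(
    metric = c("sampled", "sublocade_referent", "cessation", "retrospective",
               "planned", "withdrawal", "craving"),
    n = c(x$n_sampled, x$n_sublocade, x$n_cessation, x$n_retrospective,
          x$n_planned, x$n_withdrawal, x$n_craving),
    denominator = c(x$n_total, x$n_sampled, x$n_sublocade, x$n_cessation,
                    x$n_cessation, x$n_cessation, NA_integer_),
    percent = c(pct_or_na(x$n_sampled, x$n_total), x$pct_sublocade,
                x$pct_cessation, x$pct_retrospective, x$pct_planned,
                x$pct_withdrawal, NA_real_)
  )
}

#' @rdname summary_report
#' @export
glance.corpus_summary <- function(x, ...) {
  tibble(
    n_total = x$n_total, n_sampled = x$n_sampled,
    n_sublocade = x$n_sublocade, pct_cessation = x$pct_cessation,
    pct_withdrawal = x$pct_withdrawal, n_authors = x$authors$n_authors,
    mean_records_per_author = x$authors$mean_records,
    sd_records_per_author = x$authors$sd_records,
    final_dose_mode = x$doses$final_dose_mode,
    mean_n_doses = x$doses$n_doses$mean
  )
}

#' @rdname summary_report
#' @param object A `corpus_summary`.
#' @export
autoplot.corpus_summary <- function(object, ...) {
  df <- object$doses$final_dose_dist
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$dose), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "final reported dose (mg buprenorphine)",
      y = "annotated records",
      title = "Final-dose distribution before cessation"
    ) +
    ggplot2::theme_minimal()
}

#' Attrition funnel plot
#'
#' Bar chart of records surviving each screening stage.
#'
#' @param screened A `screened_corpus` from [screen_corpus()].
#' @return A ggplot object.
#' @export
plot_attrition <- function(screened) {
  stopifnot(inherits(screened, "screened_corpus"))
  df <- mutate(screened$attrition,
               stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n_out)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_out), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "records retained",
                  title = "Screening attrition") +
    ggplot2::theme_minimal()
}

#' Serialize a corpus summary to JSON
#'
#' Writes all counts, percentages and distributions plus a provenance block
#' (no timestamps, so identical runs produce identical bytes).
#'
#' @param x A `corpus_summary`.
#' @param path Output path.
#' @param provenance Optional named list echoed under `"provenance"`.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path, provenance = NULL) {
  payload <- list(
    provenance = provenance,
    counts = list(
      n_total = x$n_total, n_sampled = x$n_sampled,
      n_sublocade = x$n_sublocade, pct_sublocade = x$pct_sublocade,
      n_cessation = x$n_cessation, pct_cessation = x$pct_cessation,
      n_retrospective = x$n_retrospective,
      pct_retrospective = x$pct_retrospective,
      n_planned = x$n_planned, pct_planned = x$pct_planned,
      n_withdrawal = x$n_withdrawal, pct_withdrawal = x$pct_withdrawal,
      n_craving = x$n_craving, n_annotated = x$n_annotated
    ),
    authors = as.list(x$authors),
    subreddit_distribution = x$subreddit_distribution,
    dose_sequence_distribution = x$doses$sequence_dist,
    final_dose_distribution = x$doses$final_dose_dist,
    final_dose_mode = x$doses$final_dose_mode,
    n_doses = as.list(x$doses$n_doses)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
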