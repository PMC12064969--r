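#' Deduplicate records by obfuscated record id
#'
#' Keeps the first occurrence (in input order) of each `record_id`; output
#' order is stable. The number of removed rows is attached as attribute
#' `n_removed`.
#'
#' @param records Tibble with a `record_id` column.
#' @return Deduplicated tibble.
#' @export
deduplicate <- function(records) {
  out <- distinct(records, .data$record_id, .keep_all = TRUE)
  attr(out, "n_removed") <- nrow(records) - nrow(out)
  out
}

#' Plan for the seeded random coding sample
#'
#' The study codes a simple random sample of the deduplicated corpus. The
#' plan fixes the sampling fraction, the rounding rule for the sample size
#' (half-up: 6082 records at 50\% give exactly 3041) and a mandatory seed so
#' the draw is reproducible.
#'
#' @param fraction Sampling fraction in (0, 1] (default 0.5).
#' @param seed Integer seed; required.
#' @return An object of class `sample_plan`.
#' @export
sample_plan <- function(fraction = 0.5, seed) {
  if (missing(seed) || is.na(suppressWarnings(as.integer(seed)))) {
    abort("sample_plan requires an integer seed")
  }
  fraction <- as.numeric(fraction)
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1) {
    abort("fraction must lie in (0, 1]")
  }
  structure(list(fraction = fraction, seed = as.integer(seed),
                 size_rule = "round_half_up"),
            class = "sample_plan")
}

#' @export
print.sample_plan <- function(x, ...) {
  cat("<sample_plan> fraction =", x$fraction, "| seed =", x$seed,
      "| size rule =", x$size_rule, "\n")
  invisible(x)
}

#' Draw the seeded random sample
#'
#' Selects `round_half_up(n * fraction)` records uniformly without
#' replacement, deterministically for a fixed seed, preserving the input's
#' relative order. The RNG state of the session is left untouched.
#'
#' @param records Tibble of (deduplicated) records.
#' @param plan A [sample_plan()].
#' @return The sampled tibble, with the plan attached as attribute
#'   `sample_plan`.
#' @export
draw_sample <- function(records, plan) {
  stopifnot(inherits(plan, "sample_plan"))
  n <- nrow(records)
  if (n == 0) {
    attr(records, "sample_plan") <- plan
    return(records)
  }
  size <- as.integer(round_half_up(n * plan$fraction))
  idx <- withr::with_seed(plan$seed, sort(sample.int(n, size)))
  out <- records[idx, , drop = FALSE]
  attr(out, "sample_plan") <- plan
  out
}

#' Sample membership table
#'
#' One row per input record with a logical `sampled` flag, for export
#' alongside the sampled subset.
#'
#' @inheritParams draw_sample
#' @return Tibble with columns `record_id`, `sampled`, `seed`, `fraction`.
#' @export
sample_membership <- function(records, plan) {
  sampled <- draw_sample(records, plan)
  tibble(
    record_id = records$record_id,
    sampled = records$record_id %in% sampled$record_id,
    seed = plan$seed,
    fraction = plan$fraction
  )
}
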