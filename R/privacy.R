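#' Configuration for salted identifier obfuscation
#'
#' Platform identifiers (post IDs, usernames) are replaced by one-way tokens:
#' a keyed SHA-256 hash of the value under a secret salt, truncated to 64
#' bits and re-encoded in base 36. The same `(value, salt)` pair always
#' yields the same token, so equality structure (records by the same author)
#' survives while the original value does not.
#'
#' @param salt Secret string; an empty salt is refused so weak obfuscation
#'   cannot happen silently. Keep the salt out of all outputs.
#' @param token_length Token length in base-36 digits (1–12, default 10).
#' @return An object of class `obfuscation_config`.
#' @export
obfuscation_config <- function(salt, token_length = 10L) {
  if (missing(salt) || !is.character(salt) || length(salt) != 1 || !nzchar(salt)) {
    abort("obfuscation requires a non-empty salt")
  }
  token_length <- as.integer(token_length)
  if (is.na(token_length) || token_length < 1L || token_length > 12L) {
    abort("token_length must be an integer between 1 and 12")
  }
  structure(list(salt = salt, token_length = token_length),
            class = "obfuscation_config")
}

#' @export
print.obfuscation_config <- function(x, ...) {
  cat("<obfuscation_config> token_length =", x$token_length,
      "(salt withheld)\n")
  invisible(x)
}

#' Obfuscate identifiers
#'
#' Deterministic one-way mapping from identifier to base-36 token under the
#' config's salt. Vectorized; `NA` maps to `NA`.
#'
#' @param values Character vector of identifiers (non-empty strings).
#' @param config An [obfuscation_config()].
#' @return Character vector of base-36 tokens of the configured length.
#' @export
obfuscate <- function(values, config) {
  stopifnot(inherits(config, "obfuscation_config"))
  values <- as.character(values)
  if (any(!is.na(values) & !nzchar(values))) {
    abort("cannot obfuscate empty identifier(s)")
  }
  .hash_base36(values, config$salt, config$token_length)
}

#' Redaction rules for personally identifiable information
#'
#' The default rule set removes email addresses, phone numbers, URLs and
#' `u/`-style username mentions. It is a floor, not a ceiling: supply extra
#' rows (label, regex pattern, replacement containing the label) for
#' study-specific PII classes. Rule order matters — URLs are redacted before
#' username mentions so `reddit.com/u/...` paths do not leave fragments.
#'
#' @param extra Optional tibble with columns `label`, `pattern`,
#'   `replacement` appended after the defaults.
#' @return Tibble of rules with columns `label`, `pattern`, `replacement`.
#' @export
redaction_rules <- function(extra = NULL) {
  rules <- tibble(
    label = c("EMAIL", "URL", "PHONE", "USERNAME_MENTION"),
    pattern = c(
      "[[:alnum:]._%+-]+@[[:alnum:].-]+\\.[A-Za-z]{2,}",
      "(?:https?://|www\\.)[^[:space:]]+",
      "\\(?\\d{3}\\)?[-. ]\\d{3}[-. ]\\d{4}",
      "(?<![[:alnum:]])/?u/[A-Za-z0-9_-]{3,}"
    ),
    replacement = c("[REDACTED_EMAIL]", "[REDACTED_URL]", "[REDACTED_PHONE]",
                    "[REDACTED_USERNAME_MENTION]")
  )
  if (!is.null(extra)) {
    extra <- as_tibble(extra)
    stopifnot(all(c("label", "pattern", "replacement") %in% names(extra)))
    rules <- bind_rows(rules, extra)
  }
  bad <- !mapply(grepl, rules$label, rules$replacement, MoreArgs = list(fixed = TRUE))
  if (any(bad)) {
    abort(paste0("replacement must contain its rule label: ",
                 paste(rules$label[bad], collapse = ", ")))
  }
  rules
}

#' Redact PII from text
#'
#' Replaces every span matching a rule with the rule's placeholder and counts
#' replacements per rule. Idempotent: placeholders never match any rule.
#'
#' @param text Character vector.
#' @param rules Tibble of rules (default [redaction_rules()]).
#' @return List with `text` (redacted character vector) and `counts`
#'   (tibble `label`, `n`).
#' @export
redact <- function(text, rules = redaction_rules()) {
  if (nrow(rules) == 0) abort("redact() needs at least one rule")
  text <- as.character(text)
  counts <- integer(nrow(rules))
  for (i in seq_len(nrow(rules))) {
    pat <- stringr::regex(rules$pattern[i])
    counts[i] <- sum(stringr::str_count(text, pat), na.rm = TRUE)
    text <- stringr::str_replace_all(text, pat, rules$replacement[i])
  }
  list(text = text, counts = tibble(label = rules$label, n = counts))
}

#' Redact PII in a record tibble
#'
#' Applies [redact()] to the `text` column and returns the tibble with
#' per-rule counts attached as attribute `redaction_counts`.
#'
#' @param records Tibble with a `text` column.
#' @param rules Tibble of rules (default [redaction_rules()]).
#' @return The records tibble with redacted `text`.
#' @export
redact_records <- function(records, rules = redaction_rules()) {
  r <- redact(records$text, rules)
  records$text <- r$text
  attr(records, "redaction_counts") <- r$counts
  records
}
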