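#' Specification for a synthetic Reddit-style corpus
#'
#' Defines the study conditions a generated corpus emulates: a dominant
#' target subreddit, a heavy-tailed records-per-author distribution, planted
#' drug-term mentions (exact spelling or a distance-1 misspelling from the
#' explicit variant list), distance-2 decoy strings that must never match,
#' cessation keywords, construct prevalences among annotatable records,
#' timestamps over the study window with an out-of-window fraction, injected
#' exact-duplicate records, and planted PII. Every planted property is
#' emitted as ground truth.
#'
#' Records per author are modelled as 1 + a negative binomial count with the
#' dispersion solved from the target mean and SD, truncated at
#' `max_records_per_author`.
#'
#' @param n_authors Number of authors (default 1100, giving roughly 5000
#'   records at the default mean).
#' @param mean_records_per_author,sd_records_per_author,max_records_per_author
#'   Moments of the per-author record count (defaults 4.5, 13.6, 275).
#' @param p_target_subreddit Probability a record sits in the target
#'   subreddit (default 0.976).
#' @param p_term_mention Probability a record's text mentions the drug term
#'   (default 0.95).
#' @param p_exact_spelling Probability a planted mention uses the exact seed
#'   spelling rather than a sampled misspelling (default 0.7).
#' @param p_decoy Probability of an additional distance-2 decoy string that
#'   must not match (default 0.05).
#' @param p_cessation_keyword Probability the text carries a cessation
#'   keyword (default 0.9).
#' @param p_cessation_construct Probability an annotatable record truly
#'   references cessation (default 0.438).
#' @param p_withdrawal_given_cessation,p_retrospective_given_cessation,p_craving_given_cessation
#'   Conditional construct prevalences (defaults 0.087, 0.828, 1/1179).
#' @param p_course_given_cessation,p_final_only_given_cessation Probabilities
#'   a cessation record reports its full dose course, or only a final dose
#'   (defaults 0.12, 0.03).
#' @param window_start,window_end Study date window (defaults 2018-03-01,
#'   2022-08-31).
#' @param p_out_of_window Fraction of records timestamped outside the window
#'   so the date filter has work to do (default 0.05).
#' @param p_submission Probability a record is a submission rather than a
#'   comment (default 0.3).
#' @param n_duplicates Number of injected exact-duplicate records
#'   (default 25).
#' @param p_pii Probability a record carries one planted PII string
#'   (default 0.02).
#' @param seed Integer seed; mandatory — the corpus is byte-identical for a
#'   fixed seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_authors = 1100,
                           mean_records_per_author = 4.5,
                           sd_records_per_author = 13.6,
                           max_records_per_author = 275,
                           p_target_subreddit = 0.976,
                           p_term_mention = 0.95,
                           p_exact_spelling = 0.7,
                           p_decoy = 0.05,
                           p_cessation_keyword = 0.9,
                           p_cessation_construct = 0.438,
                           p_withdrawal_given_cessation = 0.087,
                           p_retrospective_given_cessation = 0.828,
                           p_craving_given_cessation = 1 / 1179,
                           p_course_given_cessation = 0.12,
                           p_final_only_given_cessation = 0.03,
                           window_start = as.Date("2018-03-01"),
                           window_end = as.Date("2022-08-31"),
                           p_out_of_window = 0.05,
                           p_submission = 0.3,
                           n_duplicates = 25,
                           p_pii = 0.02,
                           seed) {
  if (missing(seed)) abort("synthetic_spec requires a seed")
  probs <- c(p_target_subreddit, p_term_mention, p_exact_spelling, p_decoy,
             p_cessation_keyword, p_cessation_construct,
             p_withdrawal_given_cessation, p_retrospective_given_cessation,
             p_craving_given_cessation, p_course_given_cessation,
             p_final_only_given_cessation, p_out_of_window, p_submission,
             p_pii)
  if (any(!is.finite(probs) | probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1]")
  }
  if (max_records_per_author < mean_records_per_author) {
    abort("infeasible spec: max_records_per_author below the target mean")
  }
  if (p_course_given_cessation + p_final_only_given_cessation > 1) {
    abort("course and final-only probabilities must sum to at most 1")
  }
  spec <- list(
    n_authors = as.integer(n_authors),
    mean_records_per_author = mean_records_per_author,
    sd_records_per_author = sd_records_per_author,
    max_records_per_author = as.integer(max_records_per_author),
    p_target_subreddit = p_target_subreddit,
    p_term_mention = p_term_mention,
    p_exact_spelling = p_exact_spelling,
    p_decoy = p_decoy,
    p_cessation_keyword = p_cessation_keyword,
    p_cessation_construct = p_cessation_construct,
    p_withdrawal_given_cessation = p_withdrawal_given_cessation,
    p_retrospective_given_cessation = p_retrospective_given_cessation,
    p_craving_given_cessation = p_craving_given_cessation,
    p_course_given_cessation = p_course_given_cessation,
    p_final_only_given_cessation = p_final_only_given_cessation,
    window_start = as.Date(window_start),
    window_end = as.Date(window_end),
    p_out_of_window = p_out_of_window,
    p_submission = p_submission,
    n_duplicates = as.integer(n_duplicates),
    p_pii = p_pii,
    seed = as.integer(seed)
  )
  structure(spec, class = "synthetic_spec")
}

# distance-2 strings verified never to contain any explicit variant
decoy_strings <- function() {
  c("sublode", "sublacode", "bublocado", "sublocaid")
}

# template vocabulary is screened at generation time so no filler sentence
# accidentally contains a drug-term variant or cessation keyword
filler_templates <- function() {
  c("the shot was fine this month and my doctor was happy with progress",
    "been on the injection for a while now and feeling steady",
    "anyone else get soreness at the injection site for a few days",
    "my insurance approved the next appointment without delay",
    "sleep has been better these weeks and energy is coming back",
    "the clinic moved my appointment and the nurse was kind about it",
    "one month in and the routine is getting easier to manage",
    "my counselor checked in today and we talked through the plan")
}

mention_templates <- function() {
  c("just got my %s injection and it went smoothly",
    "thinking about %s and how this month has gone",
    "my doctor suggested %s at the visit today",
    "week three on %s and the soreness is mild",
    "switching to %s was the best call i made this year")
}

keyword_templates <- function() {
  c("i plan to %s treatment soon with support from my doctor",
    "we talked about how to %s the medication next month",
    "after the %s dose i will see how i feel week to week",
    "my %s plan has been on my mind all week")
}

decoy_templates <- function() {
  c("someone wrote %s but i think they meant a different medication",
    "saw the word %s in an old thread and got confused")
}

# dose-course pool: milligram sequences with 100 mg as the modal final dose
course_pool <- function() {
  list(
    list(course = c(300L), w = 0.07),
    list(course = c(100L), w = 0.06),
    list(course = c(300L, 100L), w = 0.10),
    list(course = c(100L, 100L), w = 0.04),
    list(course = c(300L, 300L, 100L), w = 0.20),
    list(course = c(300L, 300L, 300L), w = 0.07),
    list(course = c(300L, 300L, 300L, 100L), w = 0.15),
    list(course = c(300L, 300L, 100L, 100L), w = 0.11),
    list(course = c(300L, 300L, 300L, 300L), w = 0.05),
    list(course = c(300L, 300L, 300L, 300L, 100L), w = 0.07),
    list(course = c(300L, 300L, 300L, 100L, 100L, 100L), w = 0.05),
    list(course = c(300L, 300L, 300L, 300L, 300L, 300L, 100L), w = 0.03)
  )
}

plant_pii <- function(kind, i) {
  switch(kind,
    email = sprintf("user%d@example.com", i),
    phone = sprintf("555-%03d-%04d", i %% 1000, 1000 + i %% 9000),
    url = sprintf("https://example.com/thread/%d", i),
    username = sprintf("u/throwaway_%d", i)
  )
}

pii_sentence <- function(kind, pii) {
  switch(kind,
    email = paste("message me at", pii),
    phone = paste("call me at", pii),
    url = paste("more details here", pii),
    username = paste("ask", pii, "about their experience")
  )
}

#' Generate a synthetic Reddit-style corpus with planted ground truth
#'
#' Produces Pushshift-dialect raw records, a per-record ground-truth table,
#' and gold annotations (keyed by the raw platform id; obfuscate them with
#' [obfuscate_annotation_ids()] to join against normalized records). Texts
#' are template-based sentences embedding the planted keywords, misspellings
#' and decoys; the generator asserts its own consistency — a record not
#' flagged as mentioning the term is guaranteed to contain no variant
#' substring, and likewise for cessation keywords.
#'
#' @param spec A [synthetic_spec()].
#' @return Object of class `synthetic_corpus`: list with `records` (raw
#'   tibble), `truth` (ground-truth tibble), `annotations` (gold annotation
#'   tibble keyed by raw id) and `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, generate_corpus_impl(spec))
}

generate_corpus_impl <- function(spec) {
  variants <- sublocade_variants()
  misspellings <- setdiff(variants, "sublocade")
  keywords <- cessation_keywords()
  off_target <- c("opiates", "suboxone", "opiatesrecovery", "addiction", "drugs")

  # per-author record counts: 1 + NB(mu, size) with size from the target SD
  mu <- spec$mean_records_per_author - 1
  excess_var <- spec$sd_records_per_author^2 - mu
  size <- if (excess_var > 0) mu^2 / excess_var else Inf
  counts <- if (is.finite(size)) {
    1L + rnbinom(spec$n_authors, size = size, mu = mu)
  } else {
    1L + rpois(spec$n_authors, mu)
  }
  counts <- pmin(counts, spec$max_records_per_author)

  authors <- paste0("redditor_", random_base36(spec$n_authors, 8))
  n <- sum(counts)
  author <- rep(authors, counts)
  ids <- random_base36(n, 8)
  while (anyDuplicated(ids)) {
    dup <- duplicated(ids)
    ids[dup] <- random_base36(sum(dup), 8)
  }

  target <- runif(n) < spec$p_target_subreddit
  subreddit <- ifelse(target,
                      sample(c("Sublocade", "sublocade"), n, replace = TRUE,
                             prob = c(0.8, 0.2)),
                      sample(off_target, n, replace = TRUE))

  in_window <- runif(n) >= spec$p_out_of_window
  start_s <- as.numeric(as.POSIXct(spec$window_start, tz = "UTC"))
  end_s <- as.numeric(as.POSIXct(spec$window_end, tz = "UTC")) + 86399
  created <- numeric(n)
  created[in_window] <- floor(runif(sum(in_window), start_s, end_s))
  n_out <- sum(!in_window)
  if (n_out) {
    before <- runif(n_out) < 0.5
    created[!in_window] <- ifelse(
      before,
      floor(runif(n_out, start_s - 365 * 86400, start_s - 1)),
      floor(runif(n_out, end_s + 1, end_s + 120 * 86400))
    )
  }

  mention <- runif(n) < spec$p_term_mention
  mention_string <- rep(NA_character_, n)
  exact <- runif(n) < spec$p_exact_spelling
  mention_string[mention & exact] <- "sublocade"
  k <- sum(mention & !exact)
  mention_string[mention & !exact] <- sample(misspellings, k, replace = TRUE)
  # some planted mentions are capitalized to exercise case-insensitive matching
  cap <- mention & runif(n) < 0.3
  shown_mention <- mention_string
  shown_mention[cap] <- paste0(toupper(substr(shown_mention[cap], 1, 1)),
                               substr(shown_mention[cap], 2, nchar(shown_mention[cap])))

  has_kw <- runif(n) < spec$p_cessation_keyword
  keyword_string <- rep(NA_character_, n)
  keyword_string[has_kw] <- sample(keywords, sum(has_kw), replace = TRUE)

  has_decoy <- runif(n) < spec$p_decoy
  decoy_string <- rep(NA_character_, n)
  decoy_string[has_decoy] <- sample(decoy_strings(), sum(has_decoy),
                                    replace = TRUE)

  has_pii <- runif(n) < spec$p_pii
  pii_kind <- rep(NA_character_, n)
  pii_kind[has_pii] <- sample(c("email", "phone", "url", "username"),
                              sum(has_pii), replace = TRUE)
  pii_string <- rep(NA_character_, n)
  w <- which(has_pii)
  pii_string[w] <- vapply(seq_along(w), function(j) plant_pii(pii_kind[w[j]], j),
                          character(1))

  fillers <- sample(filler_templates(), n, replace = TRUE)
  text <- fillers
  w <- which(mention)
  text[w] <- paste(text[w],
                   sprintf(sample(mention_templates(), length(w), replace = TRUE),
                           shown_mention[w]), sep = ". ")
  w <- which(has_kw)
  text[w] <- paste(text[w],
                   sprintf(sample(keyword_templates(), length(w), replace = TRUE),
                           keyword_string[w]), sep = ". ")
  w <- which(has_decoy)
  text[w] <- paste(text[w],
                   sprintf(sample(decoy_templates(), length(w), replace = TRUE),
                           decoy_string[w]), sep = ". ")
  w <- which(has_pii)
  text[w] <- paste(text[w],
                   vapply(w, function(i) pii_sentence(pii_kind[i], pii_string[i]),
                          character(1)), sep = ". ")

  # self-check: planted flags must agree with the assembled text
  lower <- tolower(text)
  leak_term <- !mention &
    Reduce(`|`, lapply(variants, function(v) grepl(v, lower, fixed = TRUE)))
  leak_kw <- !has_kw &
    Reduce(`|`, lapply(keywords, function(k) grepl(k, lower, fixed = TRUE)))
  if (any(leak_term) || any(leak_kw)) {
    abort("internal generator error: template text leaks a planted keyword")
  }

  is_sub <- runif(n) < spec$p_submission
  first_split <- regexpr(". ", text, fixed = TRUE)
  title <- ifelse(first_split > 0, substr(text, 1, first_split - 1), text)
  selftext <- ifelse(first_split > 0,
                     substr(text, first_split + 2, nchar(text)), "")

  records <- tibble(
    id = ids,
    author = author,
    created_utc = created,
    subreddit = subreddit,
    title = ifelse(is_sub, title, NA_character_),
    selftext = ifelse(is_sub, selftext, NA_character_),
    body = ifelse(is_sub, NA_character_, text)
  )

  truth <- tibble(
    id = ids,
    author = author,
    target_subreddit = target,
    has_term_mention = mention,
    mention_string = mention_string,
    has_cessation_keyword = has_kw,
    keyword_string = keyword_string,
    has_decoy = has_decoy,
    decoy_string = decoy_string,
    in_window = in_window,
    has_pii = has_pii,
    pii_string = pii_string,
    is_duplicate_of = NA_character_
  )

  # inject exact duplicates (same id, same content), appended at the end
  n_dup <- min(spec$n_duplicates, n)
  if (n_dup > 0) {
    dup_idx <- sample.int(n, n_dup)
    dup_records <- records[dup_idx, ]
    dup_truth <- truth[dup_idx, ]
    dup_truth$is_duplicate_of <- dup_truth$id
    records <- bind_rows(records, dup_records)
    truth <- bind_rows(truth, dup_truth)
  }

  # constructs and gold annotations for records that reach manual coding:
  # referent (mention or target subreddit), cessation keyword, in window
  annotatable <- mention[seq_len(n)] | target
  annotatable <- annotatable & has_kw & in_window
  a_idx <- which(annotatable)
  m <- length(a_idx)
  construct <- rep(NA, nrow(truth))
  withdrawal <- rep(NA, nrow(truth))
  retrospective <- rep(NA, nrow(truth))
  craving <- rep(NA, nrow(truth))
  cflag <- runif(m) < spec$p_cessation_construct
  construct[a_idx] <- cflag
  withdrawal[a_idx] <- cflag & runif(m) < spec$p_withdrawal_given_cessation
  retrospective[a_idx] <- ifelse(cflag,
                                 runif(m) < spec$p_retrospective_given_cessation,
                                 NA)
  craving[a_idx] <- cflag & runif(m) < spec$p_craving_given_cessation
  truth$annotatable <- c(annotatable, rep(FALSE, nrow(truth) - n))
  truth$cessation_construct <- construct
  truth$withdrawal_construct <- withdrawal
  truth$retrospective <- retrospective
  truth$craving_construct <- craving

  ann <- empty_annotations(m)
  ann$record_id <- ids[a_idx]
  ann$sublocade <- 1L
  ann$any_cessation <- as.integer(cflag)
  intent <- cflag & runif(m) < 0.75
  ann$intentional_cessation <- as.integer(intent)
  ann$circumstantial_cessation <- as.integer(cflag & !intent)
  wd <- withdrawal[a_idx]
  within <- wd & runif(m) < 0.5
  ann$within_course_withdrawal <- as.integer(within)
  ann$postcourse_withdrawal <- as.integer(wd & !within)
  ann$opioid_craving <- as.integer(craving[a_idx])
  ann$cessation_timing <- ifelse(cflag,
                                 ifelse(retrospective[a_idx], "retrospective",
                                        "planned"),
                                 NA_character_)

  # dose reporting among cessation records
  pool <- course_pool()
  pw <- vapply(pool, function(x) x$w, numeric(1))
  u <- runif(m)
  has_course <- cflag & u < spec$p_course_given_cessation
  final_only <- cflag & !has_course &
    u < spec$p_course_given_cessation + spec$p_final_only_given_cessation
  ci <- which(has_course)
  if (length(ci)) {
    picks <- sample.int(length(pool), length(ci), replace = TRUE, prob = pw)
    ann$course_of_treatment[ci] <- lapply(picks, function(p) pool[[p]]$course)
    ann$number_of_doses[ci] <- vapply(ann$course_of_treatment[ci], length,
                                      integer(1))
    ann$final_dosage[ci] <- vapply(ann$course_of_treatment[ci],
                                   function(x) x[length(x)], integer(1))
    ann$duration_sublocade[ci] <- ann$number_of_doses[ci]
    ann$duration_buprenorphine[ci] <- ann$duration_sublocade[ci] +
      rpois(length(ci), 2)
    ann$duration_moud[ci] <- ann$duration_buprenorphine[ci] +
      rpois(length(ci), 3)
  }
  fi <- which(final_only)
  if (length(fi)) {
    ann$final_dosage[fi] <- sample(c(100L, 300L, 50L, 150L, 200L), length(fi),
                                   replace = TRUE,
                                   prob = c(0.6, 0.25, 0.05, 0.05, 0.05))
  }
  prior <- cflag & runif(m) < 0.15
  ann$prior_moud[prior] <- sample(c("suboxone", "methadone", "subutex"),
                                  sum(prior), replace = TRUE,
                                  prob = c(0.7, 0.2, 0.1))

  structure(
    list(records = records, truth = truth, annotations = ann, spec = spec),
    class = "synthetic_corpus"
  )
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("<synthetic_corpus> ", nrow(x$records), " record(s), ",
      length(unique(x$truth$author)), " author(s), ",
      sum(!is.na(x$truth$is_duplicate_of)), " injected duplicate(s)\n", sep = "")
  invisible(x)
}

#' Re-key gold annotations with obfuscated record ids
#'
#' Generator annotations are keyed by the raw platform id; downstream stages
#' operate on salted tokens. This maps the keys under the run's obfuscation
#' config so annotations join against normalized records.
#'
#' @param annotations Annotation tibble keyed by raw id.
#' @param config An [obfuscation_config()].
#' @return The annotation tibble with obfuscated `record_id`.
#' @export
obfuscate_annotation_ids <- function(annotations, config) {
  annotations$record_id <- obfuscate(annotations$record_id, config)
  annotations
}

#' Screening recovery against generator ground truth
#'
#' Compares each screening gate's retained set with the generator's planted
#' flags, at the unique-record level: the term gate against planted
#' mentions, the context gate against planted target-subreddit membership,
#' the parallel referent gate against their union, the cessation gate
#' against planted keywords (among true referents), and the date window
#' against planted in-window timestamps. In a clean corpus (no decoys, no
#' keyword leakage — which the generator guarantees by construction)
#' precision and recall are 1 at every gate.
#'
#' @param screened A `screened_corpus` from [screen_corpus()].
#' @param truth The generator's ground-truth tibble.
#' @param config The [obfuscation_config()] used to normalize the corpus
#'   (needed to map raw truth ids onto tokens).
#' @return Tibble with columns `stage`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`.
#' @export
evaluate_recovery <- function(screened, truth, config) {
  stopifnot(inherits(screened, "screened_corpus"))
  tr <- distinct(truth, .data$id, .keep_all = TRUE)
  tr$record_id <- obfuscate(tr$id, config)
  ids <- screened$stage_ids
  if (is.null(ids)) abort("screened corpus lacks stage membership")
  if (!all(unlist(ids) %in% tr$record_id)) {
    abort("id mismatch: screened corpus does not derive from this ground truth")
  }
  confusion <- function(predicted, positive) {
    tp <- sum(predicted %in% positive)
    fp <- length(predicted) - tp
    fn <- sum(!positive %in% predicted)
    tibble(tp = tp, fp = fp, fn = fn,
           precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
           recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
  }
  term_pred <- ids$term_keyword
  ctx_pred <- ids$subreddit_context
  referent_truth <- tr$record_id[tr$has_term_mention | tr$target_subreddit]
  cess_truth <- tr$record_id[(tr$has_term_mention | tr$target_subreddit) &
                               tr$has_cessation_keyword]
  window_truth <- tr$record_id[tr$record_id %in% cess_truth & tr$in_window]
  rows <- list(
    term_gate = confusion(term_pred, tr$record_id[tr$has_term_mention]),
    context_gate = confusion(ctx_pred, tr$record_id[tr$target_subreddit]),
    referent_gate = confusion(ids$referent, referent_truth),
    cessation_gate = confusion(ids$cessation, cess_truth),
    date_window = confusion(ids$window, window_truth)
  )
  out <- bind_rows(rows, .id = "stage")
  out
}
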