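test_that("edit_distance matches known values and the adist oracle", {
  expect_equal(edit_distance("sublocade", "sublocade"), 0L)
  expect_equal(edit_distance("sublocade", "subocade"), 1L)
  expect_equal(edit_distance("kitten", "sitting"), 3L)
  expect_equal(edit_distance("", "abc"), 3L)
  expect_equal(edit_distance("abc", ""), 3L)
  # random strings against the independent dynamic-programming oracle
  withr::with_seed(5, {
    a <- replicate(60, paste(sample(letters[1:5], sample(0:8, 1), TRUE),
                             collapse = ""))
    b <- replicate(60, paste(sample(letters[1:5], sample(0:8, 1), TRUE),
                             collapse = ""))
  })
  expect_equal(edit_distance(a, b, case_insensitive = FALSE),
               as.integer(mapply(function(x, y) utils::adist(x, y), a, b,
                                 USE.NAMES = FALSE)))
  # symmetry and case folding
  expect_equal(edit_distance(a, b), edit_distance(b, a))
  expect_equal(edit_distance("SubLocade", "sublocade"), 0L)
})

test_that("every explicit variant is within distance 1 of the seed term", {
  v <- sublocade_variants()
  expect_length(v, 20)
  expect_true(all(edit_distance("sublocade", v, case_insensitive = TRUE) <= 1))
})

test_that("enumerate_variants equals brute-force generate-and-filter", {
  expect_equal(enumerate_variants("ab", 0, c("a", "b")), "ab")
  e <- enumerate_variants("ab", 1, c("a", "b"))
  expect_setequal(e, c("ab", "a", "b", "aa", "bb", "aab", "aba", "abb", "bab"))
  cases <- list(
    list(term = "ab", d = 1, ab = c("a", "b")),
    list(term = "ab", d = 2, ab = c("a", "b")),
    list(term = "abc", d = 1, ab = c("a", "b", "c")),
    list(term = "abcd", d = 1, ab = c("a", "b", "c", "d")),
    list(term = "aa", d = 2, ab = c("a", "b", "c"))
  )
  for (cs in cases) {
    expect_equal(enumerate_variants(cs$term, cs$d, cs$ab),
                 brute_force_variants(cs$term, cs$d, cs$ab),
                 label = paste(cs$term, cs$d))
  }
})

test_that("the distance-1 neighbourhood of the seed term is exact", {
  e <- enumerate_variants("sublocade", 1, letters)
  # every Table-style variant except the seed itself is a member
  expect_true(all(sublocade_variants() %in% e))
  # the set is exactly the distance<=1 ball (filter property, both directions)
  expect_true(all(utils::adist("sublocade", e) <= 1))
  # distinct neighbours of a 9-letter word with no repeated letters:
  # 1 + 9 deletions + 25*9 substitutions + (26*10 - 9) insertions
  expect_length(e, 1 + 9 + 225 + 251)
  expect_error(enumerate_variants("sublocade", 3, letters, cap = 1000),
               "cap")
})

test_that("match_term finds explicit variants as case-insensitive substrings", {
  m <- match_term(c("My Sublocades are working", "", "suboxone only today"),
                  default_criteria)
  expect_equal(m$matched, c(TRUE, FALSE, FALSE))
  # "Sublocades" contains both the seed spelling and the plural variant
  expect_setequal(m$matches[[1]]$keyword, c("sublocade", "sublocades"))
  expect_equal(unique(m$matches[[1]]$position), 4L)
})

test_that("generative token mode matches any token within the distance", {
  crit <- screening_criteria(match_mode = "generative_token")
  m <- match_term(c("got my sublocaid shot", "sublocadexx is not a token match",
                    "nothing here"), crit)
  # sublocaid is distance 2: no match; sublocadexx distance 2: no match
  expect_equal(m$matched, c(FALSE, FALSE, FALSE))
  m2 <- match_term(c("got my Subocade shot", "sublocade here"), crit)
  expect_equal(m2$matched, c(TRUE, TRUE))
})

test_that("match_cessation has the documented false-positive surface", {
  m <- match_cessation(c("planning to taper off next month",
                         "at last I feel normal",
                         "no relevant words here"), default_criteria)
  expect_equal(m$matched, c(TRUE, TRUE, FALSE))
  expect_equal(m$matches[[1]]$keyword[1], "taper")
  expect_equal(m$matches[[2]]$keyword[1], "last")
  # token mode is stricter: "last" inside "lastly" no longer matches
  t1 <- match_cessation("we lastly spoke", default_criteria, mode = "token")
  t2 <- match_cessation("the last shot", default_criteria, mode = "token")
  expect_false(t1$matched)
  expect_true(t2$matched)
})

test_that("matching is invariant under case changes of the input", {
  texts <- c("my SUBLOCADE and TAPER plan", "Subloccade, Stop now",
             "nothing to see")
  up <- toupper(texts); lo <- tolower(texts)
  expect_equal(match_term(up, default_criteria)$matched,
               match_term(lo, default_criteria)$matched)
  expect_equal(match_cessation(up, default_criteria)$matched,
               match_cessation(lo, default_criteria)$matched)
})

test_that("substring matching agrees with a naive all-positions scan", {
  texts <- random_texts(400, sublocade_variants(), p_plant = 0.4, seed = 21)
  expect_equal(match_term(texts, default_criteria)$matched,
               naive_substring_match(texts, sublocade_variants()))
  texts2 <- random_texts(400, cessation_keywords(), p_plant = 0.4, seed = 22)
  expect_equal(match_cessation(texts2, default_criteria)$matched,
               naive_substring_match(texts2, cessation_keywords()))
})

test_that("context and window predicates follow the inclusion rules", {
  expect_true(match_context("sublocade", default_criteria))
  expect_true(match_context("Sublocade", default_criteria))
  expect_false(match_context("opiates", default_criteria))
  expect_true(within_window(as.Date("2018-03-01"), default_criteria))
  expect_false(within_window(as.Date("2018-02-28"), default_criteria))
  expect_true(within_window(as.Date("2022-08-31"), default_criteria))
  expect_false(within_window(as.Date("2022-09-01"), default_criteria))
})

test_that("criteria constructor rejects out-of-distance variants and bad windows", {
  expect_error(screening_criteria(explicit_variants = c("sublocade", "methadone")),
               "beyond max_distance")
  expect_error(screening_criteria(window_start = "2023-01-01",
                                  window_end = "2022-01-01"),
               "window_start")
})

test_that("screen_corpus applies the gates in study order with attrition counts", {
  norm <- tiny_normalized()
  screened <- screen_corpus(norm, default_criteria)
  # record 3 (r/opiates submission) matches by term keyword; all pass
  expect_equal(nrow(screened$records), 3)
  expect_equal(screened$attrition$stage,
               c("referent_gate", "deduplication", "cessation_gate",
                 "date_window"))
  expect_equal(screened$attrition$n_out, c(3L, 3L, 3L, 3L))
  expect_true("term_keyword" %in% screened$records$match_criteria[[3]])
  expect_true("subreddit_context" %in% screened$records$match_criteria[[1]])
  expect_true(all(vapply(screened$records$match_criteria,
                         function(mc) "cessation_keyword" %in% mc, logical(1))))
  expect_identical(tidy(screened), screened$attrition)
})

test_that("duplicated records leave one survivor after the dedup stage", {
  norm <- tiny_normalized()
  doubled <- dplyr::bind_rows(norm, norm[1, ])
  screened <- screen_corpus(doubled, default_criteria)
  att <- screened$attrition
  expect_equal(att$n_removed[att$stage == "deduplication"], 1L)
  expect_equal(nrow(screened$records), 3)
})

test_that("screening is idempotent and zero-safe", {
  norm <- tiny_normalized()
  s1 <- screen_corpus(norm, default_criteria)
  s2 <- screen_corpus(s1$records[names(norm)], default_criteria)
  expect_setequal(s2$records$record_id, s1$records$record_id)
  expect_equal(s2$attrition$n_removed, rep(0L, 4))
  empty <- screen_corpus(norm[0, ], default_criteria)
  expect_equal(nrow(empty$records), 0)
  expect_equal(empty$attrition$n_in, rep(0L, 4))
})

test_that("out-of-window and keyword-free records are removed at their gates", {
  raw <- tiny_raw_corpus()
  raw$created_utc[2] <- as.numeric(as.POSIXct("2023-05-01", tz = "UTC"))
  raw$body[1] <- "Starting sublocade today"  # no cessation keyword
  norm <- normalize_records(raw, test_obf)
  screened <- screen_corpus(norm, default_criteria)
  att <- screened$attrition
  expect_equal(att$n_removed[att$stage == "cessation_gate"], 1L)
  expect_equal(att$n_removed[att$stage == "date_window"], 1L)
  expect_equal(nrow(screened$records), 1)
})
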