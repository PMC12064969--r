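test_that("the same seed gives a byte-identical corpus and ground truth", {
  s <- synthetic_spec(n_authors = 70, seed = 101)
  g1 <- generate_corpus(s)
  g2 <- generate_corpus(s)
  expect_identical(g1$records, g2$records)
  expect_identical(g1$truth, g2$truth)
  expect_identical(g1$annotations, g2$annotations)
  g3 <- generate_corpus(synthetic_spec(n_authors = 70, seed = 102))
  expect_false(identical(g1$records, g3$records))
})

test_that("forced plants and duplicates obey the spec exactly", {
  g <- generate_corpus(synthetic_spec(n_authors = 40, p_term_mention = 1,
                                      p_decoy = 0, n_duplicates = 5,
                                      seed = 9))
  originals <- is.na(g$truth$is_duplicate_of)
  expect_true(all(g$truth$has_term_mention[originals]))
  expect_equal(sum(!originals), 5L)
  dup_ids <- g$truth$id[!originals]
  expect_true(all(dup_ids %in% g$truth$id[originals]))
  # duplicates are exact copies of their originals
  for (d in dup_ids) {
    rows <- g$records[g$records$id == d, ]
    expect_equal(nrow(unique(rows)), 1L)
  }
})

test_that("infeasible specs are refused", {
  expect_error(synthetic_spec(seed = 1, p_term_mention = 1.4), "probabilities")
  expect_error(synthetic_spec(seed = 1, mean_records_per_author = 10,
                              max_records_per_author = 5), "infeasible")
  expect_error(synthetic_spec(n_authors = 10), "seed")
})

test_that("ground-truth flags are consistent with the generated text", {
  g <- generate_corpus(synthetic_spec(n_authors = 80, seed = 33))
  norm <- normalize_records(g$records, test_obf)
  tr <- g$truth
  term <- match_term(norm$text, default_criteria)$matched
  expect_equal(term, tr$has_term_mention)
  cess <- match_cessation(norm$text, default_criteria)$matched
  expect_equal(cess, tr$has_cessation_keyword)
  expect_equal(within_window(norm$created_date, default_criteria), tr$in_window)
  expect_equal(norm$subreddit == "sublocade", tr$target_subreddit)
})

test_that("planted misspellings from the explicit list are always caught", {
  g <- generate_corpus(synthetic_spec(n_authors = 120, p_term_mention = 1,
                                      p_exact_spelling = 0, seed = 13))
  norm <- normalize_records(g$records, test_obf)
  m <- match_term(norm$text, default_criteria)
  expect_true(all(m$matched))
  expect_true(all(g$truth$mention_string %in% sublocade_variants()))
})

test_that("distance-2 decoys never match the explicit variant list", {
  g <- generate_corpus(synthetic_spec(n_authors = 60, p_term_mention = 0,
                                      p_decoy = 1, seed = 27))
  norm <- normalize_records(g$records, test_obf)
  expect_true(all(edit_distance("sublocade", g$truth$decoy_string) == 2))
  m <- match_term(norm$text, default_criteria)
  expect_false(any(m$matched))
})

test_that("per-author counts approach the heavy-tailed targets at scale", {
  g <- generate_corpus(synthetic_spec(n_authors = 4000, n_duplicates = 0,
                                      seed = 201))
  counts <- as.integer(table(g$truth$author))
  expect_equal(mean(counts), 4.5, tolerance = 0.15)
  expect_equal(sd(counts), 13.6, tolerance = 0.25)
  expect_true(max(counts) <= 275)
  expect_true(min(counts) >= 1)
})

test_that("screening recovers the planted ground truth exactly", {
  g <- generate_corpus(synthetic_spec(n_authors = 150, seed = 61))
  norm <- normalize_records(g$records, test_obf)
  screened <- screen_corpus(norm, default_criteria)
  rec <- evaluate_recovery(screened, g$truth, test_obf)
  expect_setequal(rec$stage, c("term_gate", "context_gate", "referent_gate",
                               "cessation_gate", "date_window"))
  # the generator guarantees no keyword leakage, so every gate is perfect
  expect_true(all(rec$precision == 1))
  expect_true(all(rec$recall == 1))
})

test_that("recovery evaluation refuses a mismatched ground truth", {
  g <- generate_corpus(synthetic_spec(n_authors = 30, seed = 71))
  norm <- normalize_records(g$records, test_obf)
  screened <- screen_corpus(norm, default_criteria)
  other_salt <- obfuscation_config("a-different-salt")
  expect_error(evaluate_recovery(screened, g$truth, other_salt),
               "id mismatch")
})

test_that("the keyword gate's construct-level false positives are quantifiable", {
  # cessation keywords over-include relative to the true cessation construct
  # (e.g. "last" in non-cessation senses); the planted truth measures by how much
  g <- generate_corpus(synthetic_spec(n_authors = 200, seed = 83))
  screened <- screen_corpus(normalize_records(g$records, test_obf),
                            default_criteria)
  tr <- dplyr::distinct(g$truth, id, .keep_all = TRUE)
  tr$record_id <- obfuscate(tr$id, test_obf)
  kept <- tr[tr$record_id %in% screened$records$record_id, ]
  construct_precision <- mean(kept$cessation_construct)
  expect_lt(construct_precision, 1)
  expect_equal(construct_precision,
               sum(tr$cessation_construct & tr$annotatable, na.rm = TRUE) /
                 sum(tr$annotatable))
})
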