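test_that("percentage reproduces printed study arithmetic", {
  expect_equal(percentage(1179, 2692), 43.8)
  expect_equal(percentage(102, 1179), 8.7)
  expect_equal(percentage(976, 1179), 82.8)
  expect_equal(percentage(203, 1179), 17.2)
  expect_equal(percentage(2968, 3041), 97.6)
  expect_equal(percentage(0, 100), 0.0)
  expect_equal(percentage(127, 160), 79.4)
  expect_error(percentage(1, 0), "denominator")
  expect_error(percentage(5, 4), "numerator")
})

test_that("rounding is half-up at the stated precision", {
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(43.75, 1), 43.8)
  expect_equal(round_half_up(43.74, 1), 43.7)
})

test_that("complementary percentages sum to about one hundred", {
  withr::with_seed(3, {
    b <- sample(1:5000, 300, replace = TRUE)
    a <- vapply(b, function(x) sample(0:x, 1), integer(1))
  })
  s <- percentage(a, b) + percentage(b - a, b)
  expect_true(all(s >= 99.9 & s <= 100.1))
})

test_that("author_stats matches hand computation with the sample-SD formula", {
  recs <- tibble::tibble(author_id = c("A", "A", "A", "B"))
  st <- author_stats(recs)
  expect_equal(st$n_authors, 2L)
  expect_equal(st$mean_records, 2.0)
  expect_equal(st$sd_records, sqrt(2))
  expect_equal(st$min_records, 1L)
  expect_equal(st$max_records, 3L)
  expect_false(st$sd_undefined)
})

test_that("author_stats handles degenerate corpora", {
  single <- author_stats(tibble::tibble(author_id = rep("A", 5)))
  expect_equal(single$mean_records, 5)
  expect_equal(single$sd_records, 0)
  expect_true(single$sd_undefined)
  empty <- author_stats(tibble::tibble(author_id = character(0)))
  expect_equal(empty$n_authors, 0L)
})

test_that("author_stats recovers generator per-author counts", {
  corpus <- generate_corpus(synthetic_spec(n_authors = 80, n_duplicates = 0,
                                           seed = 6))
  norm <- normalize_records(corpus$records, test_obf)
  st <- author_stats(norm)
  truth_counts <- table(corpus$truth$author)
  expect_equal(st$n_authors, length(truth_counts))
  expect_equal(st$mean_records, mean(truth_counts))
  expect_equal(st$sd_records, sd(truth_counts))
  expect_equal(st$max_records, max(truth_counts))
})

test_that("dose distributions count sequences and pool final doses", {
  ann <- empty_annotations(4)
  ann$record_id <- paste0("r", 1:4)
  ann$sublocade <- 1L
  ann$course_of_treatment <- list(300L, 300L, 100L, integer(0))
  ann$number_of_doses <- c(1L, 1L, 1L, NA)
  ann$final_dosage <- c(300L, 300L, 100L, 100L)  # r4 reports final dose only
  dd <- dose_distributions(ann)
  expect_equal(dd$sequence_dist$course, c("300", "100"))
  expect_equal(dd$sequence_dist$n, c(2L, 1L))
  expect_equal(dd$final_dose_dist$n[dd$final_dose_dist$dose == 100], 2L)
  expect_equal(dd$final_dose_dist$n[dd$final_dose_dist$dose == 300], 2L)
  # final-dose-only records never enter the sequence table
  expect_equal(sum(dd$sequence_dist$n), 3L)
  expect_equal(sum(dd$final_dose_dist$n), 4L)
})

test_that("n_doses summary uses mean, sample SD, median and Q3-Q1", {
  ann <- empty_annotations(5)
  ann$record_id <- paste0("r", 1:5)
  ann$sublocade <- 1L
  ann$number_of_doses <- c(1L, 2L, 3L, 5L, 9L)
  nd <- dose_distributions(ann)$n_doses
  expect_equal(nd$mean, 4)
  expect_equal(nd$sd, sd(c(1, 2, 3, 5, 9)))
  expect_equal(nd$median, 3)
  expect_equal(nd$iqr, unname(diff(quantile(c(1, 2, 3, 5, 9), c(.25, .75)))))
})

test_that("planted modal final dose is recovered", {
  corpus <- generate_corpus(synthetic_spec(n_authors = 400, seed = 19))
  dd <- dose_distributions(corpus$annotations)
  expect_equal(dd$final_dose_mode, 100L)
})

test_that("summary_report populates every field with traceable denominators", {
  corpus <- generate_corpus(synthetic_spec(n_authors = 150, seed = 44))
  norm <- normalize_records(corpus$records, test_obf)
  screened <- screen_corpus(norm, default_criteria)
  deduped <- deduplicate(screened$records)
  sampled <- draw_sample(deduped, sample_plan(0.5, seed = 44))
  ann <- obfuscate_annotation_ids(corpus$annotations, test_obf)
  cs <- summary_report(sampled, ann, n_total = nrow(deduped),
                       criteria = default_criteria)
  expect_s3_class(cs, "corpus_summary")
  expect_equal(cs$n_sampled, nrow(sampled))
  expect_equal(cs$pct_cessation, percentage(cs$n_cessation, cs$n_sublocade))
  expect_equal(cs$n_retrospective + cs$n_planned, cs$n_cessation)
  td <- tidy(cs)
  expect_true(all(c("metric", "n", "denominator", "percent") %in% names(td)))
  expect_equal(td$n[td$metric == "cessation"], cs$n_cessation)
  gl <- glance(cs)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$final_dose_mode, cs$doses$final_dose_mode)
  # distribution frequencies sum to their denominators
  expect_equal(sum(cs$subreddit_distribution$n), cs$n_sampled)
  p <- autoplot(cs)
  expect_s3_class(p, "ggplot")
})

test_that("an all-zero annotation corpus yields zero counts and 0.0 percents", {
  records <- tibble::tibble(record_id = paste0("r", 1:4),
                            author_id = "a", subreddit = "sublocade")
  ann <- empty_annotations(4)
  ann$record_id <- records$record_id
  ann$sublocade <- 0L
  ann[c("any_cessation", "intentional_cessation", "circumstantial_cessation",
        "within_course_withdrawal", "postcourse_withdrawal",
        "opioid_craving")] <- 0L
  cs <- summary_report(records, ann)
  expect_equal(cs$n_sublocade, 0L)
  expect_equal(cs$pct_sublocade, 0.0)
  expect_true(is.na(cs$pct_cessation))  # denominator zero is undefined
  expect_equal(cs$n_craving, 0L)
})
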