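make_annotation <- function(...) {
  a <- empty_annotations(1)
  a$record_id <- "rec1"
  a$sublocade <- 1L
  args <- list(...)
  for (nm in names(args)) a[[nm]] <- args[[nm]]
  a
}

test_that("parse_course handles the documented formats", {
  expect_equal(parse_course("100, 300, 300, 100"), c(100L, 300L, 300L, 100L))
  expect_equal(parse_course(""), integer(0))
  expect_equal(parse_course("300"), 300L)
  expect_equal(parse_course(" 100 ,300 "), c(100L, 300L))
  expect_error(parse_course("100, twice, 300"), "twice")
  expect_equal(format_course(c(100L, 300L)), "100, 300")
  expect_equal(parse_course(format_course(integer(0))), integer(0))
})

test_that("the codebook manifest is complete and unambiguous", {
  fields <- codebook_fields()
  expect_equal(anyDuplicated(fields$field_name), 0L)
  expect_equal(anyDuplicated(fields$column), 0L)
  ann_cols <- fields$column[fields$where == "annotation"]
  expect_true(all(ann_cols %in% names(empty_annotations())))
  # the timing split reported alongside the constructs is carried too
  expect_true("cessation_timing" %in% names(empty_annotations()))
})

test_that("consistent annotations validate clean", {
  a <- make_annotation(any_cessation = 1L, intentional_cessation = 1L,
                       course_of_treatment = list(c(100L, 300L, 300L, 100L)),
                       number_of_doses = 4L, final_dosage = 100L,
                       cessation_timing = "retrospective")
  expect_equal(nrow(validate_annotations(a)), 0)
})

test_that("each seeded contradiction is caught by its rule", {
  cases <- list(
    list(ann = make_annotation(intentional_cessation = 1L, any_cessation = 0L),
         rule = "cessation_implies_any"),
    list(ann = make_annotation(sublocade = 0L, any_cessation = 1L),
         rule = "construct_implies_referent"),
    list(ann = make_annotation(any_cessation = 1L,
                               course_of_treatment = list(300L),
                               number_of_doses = 2L),
         rule = "course_length"),
    list(ann = make_annotation(any_cessation = 1L,
                               course_of_treatment = list(c(300L, 100L)),
                               number_of_doses = 2L, final_dosage = 300L),
         rule = "final_dose_consistent"),
    list(ann = make_annotation(final_dosage = 400L), rule = "dose_range"),
    list(ann = make_annotation(duration_sublocade = 9L,
                               duration_buprenorphine = 4L),
         rule = "duration_ordering"),
    list(ann = make_annotation(sublocade = 2L), rule = "binary_domain"),
    list(ann = make_annotation(cessation_timing = "sometime"),
         rule = "timing_domain"),
    list(ann = make_annotation(any_cessation = 0L,
                               cessation_timing = "planned"),
         rule = "timing_implies_cessation")
  )
  for (cs in cases) {
    report <- validate_annotations(cs$ann)
    expect_true(cs$rule %in% report$rule, label = cs$rule)
    expect_true(all(report$severity[report$rule == cs$rule] == "error"))
  }
})

test_that("implausible in-range doses warn rather than error", {
  a <- make_annotation(final_dosage = 17L)
  report <- validate_annotations(a)
  expect_equal(report$rule, "dose_oddity")
  expect_equal(report$severity, "warning")
})

test_that("generator gold annotations validate clean across seeds", {
  for (seed in c(2, 14, 86)) {
    corpus <- generate_corpus(synthetic_spec(n_authors = 60, seed = seed))
    report <- validate_annotations(corpus$annotations)
    expect_equal(nrow(report), 0, label = paste("seed", seed))
  }
})

test_that("annotations survive the CSV round trip", {
  corpus <- generate_corpus(synthetic_spec(n_authors = 40, seed = 55))
  path <- tempfile(fileext = ".csv")
  write_annotations(corpus$annotations, path)
  back <- read_annotations(path)
  expect_equal(nrow(back), nrow(corpus$annotations))
  expect_identical(back$course_of_treatment, corpus$annotations$course_of_treatment)
  expect_equal(back$any_cessation, corpus$annotations$any_cessation)
  expect_equal(back$cessation_timing, corpus$annotations$cessation_timing)
})

test_that("join_annotations flags coverage, orphans and conflicts", {
  records <- tibble::tibble(record_id = c("r1", "r2", "r3"), text = "t")
  ann <- make_annotation()
  ann$record_id <- "r1"
  joined <- join_annotations(records, ann)
  expect_equal(joined$annotated, c(TRUE, FALSE, FALSE))
  orphan <- dplyr::bind_rows(ann, dplyr::mutate(ann, record_id = "zzz"))
  expect_message(j2 <- join_annotations(records, orphan), "orphan")
  expect_equal(attr(j2, "orphans"), "zzz")
  dup <- dplyr::bind_rows(ann, ann)
  expect_error(join_annotations(records, dup), "duplicate annotation")
})

test_that("join coverage matches generator ground truth", {
  corpus <- generate_corpus(synthetic_spec(n_authors = 60, seed = 77))
  norm <- normalize_records(corpus$records, test_obf)
  screened <- screen_corpus(norm, default_criteria)
  ann <- obfuscate_annotation_ids(corpus$annotations, test_obf)
  joined <- join_annotations(screened$records, ann)
  # every screened record is annotatable by construction, so coverage is full
  expect_true(all(joined$annotated))
  expect_length(attr(joined, "orphans"), 0)
})
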