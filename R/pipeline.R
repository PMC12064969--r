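#' Pipeline configuration
#'
#' Collects everything a run needs: input/output paths, the screening
#' criteria, the sample plan, the obfuscation salt, and (for `generate`) the
#' synthetic-corpus spec. Can be built from a YAML or JSON file with
#' [read_pipeline_config()]. All seeds and the criteria are echoed into
#' every artifact's provenance block.
#'
#' @param out_dir Directory for stage artifacts.
#' @param input Path to the input JSON Lines corpus; defaults to the
#'   generated corpus inside `out_dir`.
#' @param salt Obfuscation salt (never written to outputs).
#' @param token_length Obfuscation token length (default 10).
#' @param criteria A [screening_criteria()] (default study criteria).
#' @param fraction Sampling fraction (default 0.5).
#' @param seed Integer seed driving generation and sampling.
#' @param synthetic A [synthetic_spec()]; defaults to the study-conditions
#'   spec under `seed`.
#' @param redaction A tibble of redaction rules (default
#'   [redaction_rules()]).
#' @param cessation_mode Cessation keyword mode, `"substring"` (default) or
#'   `"token"`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            input = file.path(out_dir, "corpus.jsonl"),
                            salt = "soclisten-default-salt",
                            token_length = 10L,
                            criteria = screening_criteria(),
                            fraction = 0.5,
                            seed = 20180301L,
                            synthetic = NULL,
                            redaction = redaction_rules(),
                            cessation_mode = "substring") {
  seed <- as.integer(seed)
  if (is.null(synthetic)) synthetic <- synthetic_spec(seed = seed)
  structure(
    list(
      out_dir = out_dir,
      input = input,
      obfuscation = obfuscation_config(salt, token_length),
      criteria = criteria,
      plan = sample_plan(fraction = fraction, seed = seed),
      seed = seed,
      synthetic = synthetic,
      redaction = redaction,
      cessation_mode = cessation_mode
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Recognised keys: `out_dir`, `input`, `salt`, `token_length`, `fraction`,
#' `seed`, `cessation_mode`, a `criteria` block (`seed_term`,
#' `max_distance`, `explicit_variants`, `cessation_keywords`,
#' `context_subreddits`, `window_start`, `window_end`, `match_mode`) and a
#' `synthetic` block with [synthetic_spec()] arguments. Unknown fields are
#' an error so typos do not silently fall back to defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param out_dir Optional override of the configured output directory.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("out_dir", "input", "salt", "token_length", "fraction", "seed",
             "criteria", "synthetic", "cessation_mode")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    abort(paste0("unknown config field(s): ", paste(extra, collapse = ", ")))
  }
  crit_args <- cfg$criteria %||% list()
  if (!is.null(crit_args$window_start)) crit_args$window_start <- as.Date(crit_args$window_start)
  if (!is.null(crit_args$window_end)) crit_args$window_end <- as.Date(crit_args$window_end)
  criteria <- do.call(screening_criteria, crit_args)
  seed <- as.integer(cfg$seed %||% 20180301L)
  syn_args <- cfg$synthetic %||% list()
  if (is.null(syn_args$seed)) syn_args$seed <- seed
  synthetic <- do.call(synthetic_spec, syn_args)
  args <- list(
    out_dir = cfg$out_dir %||% out_dir %||% abort("config needs out_dir"),
    salt = cfg$salt %||% "soclisten-default-salt",
    token_length = cfg$token_length %||% 10L,
    criteria = criteria,
    fraction = cfg$fraction %||% 0.5,
    seed = seed,
    synthetic = synthetic,
    cessation_mode = cfg$cessation_mode %||% "substring"
  )
  if (!is.null(cfg$input)) args$input <- cfg$input
  if (!is.null(out_dir)) args$out_dir <- out_dir
  do.call(pipeline_config, args)
}

artifact <- function(config, name) file.path(config$out_dir, name)

require_artifact <- function(config, name, producer) {
  p <- artifact(config, name)
  if (!file.exists(p)) {
    abort(sprintf("missing artifact '%s': run the '%s' stage first", name,
                  producer))
  }
  p
}

provenance_block <- function(config) {
  list(
    package = "soclisten",
    seed = config$seed,
    fraction = config$plan$fraction,
    criteria = list(
      seed_term = config$criteria$seed_term,
      max_distance = config$criteria$max_distance,
      explicit_variants = config$criteria$explicit_variants,
      cessation_keywords = config$criteria$cessation_keywords,
      context_subreddits = config$criteria$context_subreddits,
      window_start = format(config$criteria$window_start),
      window_end = format(config$criteria$window_end),
      match_mode = config$criteria$match_mode
    )
  )
}

write_csv_with_provenance <- function(df, path, config) {
  prov <- sprintf("# provenance: soclisten seed=%d fraction=%g window=%s..%s",
                  config$seed, config$plan$fraction,
                  format(config$criteria$window_start),
                  format(config$criteria$window_end))
  writeLines(prov, path)
  suppressWarnings(readr::write_csv(df, path, append = TRUE, col_names = TRUE))
  invisible(path)
}

read_csv_skipping_provenance <- function(path, ...) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE, ...)
}

#' Run the social-listening pipeline
#'
#' Executes one stage (or `all` of them in study order) against file
#' artifacts under `config$out_dir`, so every stage is independently
#' re-runnable and inspectable:
#' \describe{
#'   \item{generate}{synthetic corpus → `corpus.jsonl`,
#'     `ground_truth.csv`, `gold_annotations.csv`}
#'   \item{screen}{ingest + normalize + screen → `screened.jsonl`,
#'     `attrition.csv`}
#'   \item{redact}{PII redaction → `redacted.jsonl`,
#'     `redaction_counts.csv`}
#'   \item{sample}{seeded 50\% draw → `sampled.jsonl`,
#'     `sample_membership.csv`}
#'   \item{validate}{annotation validation → `annotations.csv`,
#'     `validation_report.csv`}
#'   \item{summarize}{descriptive statistics → `summary.json`,
#'     `summary.txt`, distribution CSVs}
#' }
#' Outputs carry a provenance block (seed, criteria) and no timestamps, so
#' two runs with the same config are byte-identical.
#'
#' @param subcommand One of `"generate"`, `"screen"`, `"redact"`,
#'   `"sample"`, `"validate"`, `"summarize"`, `"all"`.
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of artifact paths (for `summarize`/`all`,
#'   also the `corpus_summary` object under `$summary`).
#' @export
run_pipeline <- function(subcommand = c("all", "generate", "screen", "redact",
                                        "sample", "validate", "summarize"),
                         config) {
  subcommand <- arg_match(subcommand)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  steps <- if (subcommand == "all") {
    c("generate", "screen", "redact", "sample", "validate", "summarize")
  } else {
    subcommand
  }
  out <- list()
  for (step in steps) {
    out <- c(out, switch(step,
      generate = stage_generate(config),
      screen = stage_screen(config),
      redact = stage_redact(config),
      sample = stage_sample(config),
      validate = stage_validate(config),
      summarize = stage_summarize(config)
    ))
  }
  invisible(out)
}

stage_generate <- function(config) {
  corpus <- generate_corpus(config$synthetic)
  p_corpus <- artifact(config, "corpus.jsonl")
  write_records(corpus$records, p_corpus)
  p_truth <- artifact(config, "ground_truth.csv")
  write_csv_with_provenance(corpus$truth, p_truth, config)
  p_gold <- artifact(config, "gold_annotations.csv")
  write_annotations(corpus$annotations, p_gold)
  inform(sprintf("generate: %d record(s), %d annotatable",
                 nrow(corpus$records), nrow(corpus$annotations)))
  list(corpus = p_corpus, ground_truth = p_truth, gold_annotations = p_gold)
}

stage_screen <- function(config) {
  input <- if (file.exists(config$input)) config$input else
    require_artifact(config, "corpus.jsonl", "generate")
  raw <- read_records(input)
  normalized <- normalize_records(raw, config$obfuscation)
  screened <- screen_corpus(normalized, config$criteria,
                            cessation_mode = config$cessation_mode)
  p_records <- artifact(config, "screened.jsonl")
  write_normalized(screened$records, p_records)
  p_att <- artifact(config, "attrition.csv")
  write_csv_with_provenance(screened$attrition, p_att, config)
  inform(sprintf("screen: %d in, %d retained", nrow(raw),
                 nrow(screened$records)))
  list(screened = p_records, attrition = p_att)
}

stage_redact <- function(config) {
  p_in <- require_artifact(config, "screened.jsonl", "screen")
  records <- read_normalized(p_in)
  redacted <- redact_records(records, config$redaction)
  p_out <- artifact(config, "redacted.jsonl")
  write_normalized(redacted, p_out)
  p_counts <- artifact(config, "redaction_counts.csv")
  write_csv_with_provenance(attr(redacted, "redaction_counts"), p_counts,
                            config)
  inform(sprintf("redact: %d span(s) redacted",
                 sum(attr(redacted, "redaction_counts")$n)))
  list(redacted = p_out, redaction_counts = p_counts)
}

stage_sample <- function(config) {
  p_in <- require_artifact(config, "redacted.jsonl", "redact")
  records <- deduplicate(read_normalized(p_in))
  membership <- sample_membership(records, config$plan)
  sampled <- draw_sample(records, config$plan)
  p_sampled <- artifact(config, "sampled.jsonl")
  write_normalized(sampled, p_sampled)
  p_members <- artifact(config, "sample_membership.csv")
  write_csv_with_provenance(membership, p_members, config)
  inform(sprintf("sample: %d of %d record(s) drawn (fraction %g, seed %d)",
                 nrow(sampled), nrow(records), config$plan$fraction,
                 config$plan$seed))
  list(sampled = p_sampled, sample_membership = p_members)
}

stage_validate <- function(config) {
  p_sampled <- require_artifact(config, "sampled.jsonl", "sample")
  p_gold <- require_artifact(config, "gold_annotations.csv", "generate")
  sampled <- read_normalized(p_sampled)
  gold <- read_annotations(p_gold)
  ann <- obfuscate_annotation_ids(gold, config$obfuscation)
  ann <- ann[ann$record_id %in% sampled$record_id, , drop = FALSE]
  report <- validate_annotations(ann)
  p_ann <- artifact(config, "annotations.csv")
  write_annotations(ann, p_ann)
  p_report <- artifact(config, "validation_report.csv")
  write_csv_with_provenance(report, p_report, config)
  inform(sprintf("validate: %d annotation(s), %d violation(s)", nrow(ann),
                 nrow(report)))
  list(annotations = p_ann, validation_report = p_report)
}

stage_summarize <- function(config) {
  p_sampled <- require_artifact(config, "sampled.jsonl", "sample")
  p_ann <- require_artifact(config, "annotations.csv", "validate")
  p_att <- require_artifact(config, "attrition.csv", "screen")
  sampled <- read_normalized(p_sampled)
  ann <- read_annotations(p_ann)
  attrition <- read_csv_skipping_provenance(p_att)
  n_total <- attrition$n_out[attrition$stage == "date_window"]
  summary <- summary_report(sampled, ann, n_total = n_total,
                            criteria = config$criteria)
  p_json <- artifact(config, "summary.json")
  write_summary_json(summary, p_json, provenance = provenance_block(config))
  p_txt <- artifact(config, "summary.txt")
  txt <- utils::capture.output(print(summary))
  writeLines(txt, p_txt)
  write_csv_with_provenance(summary$subreddit_distribution,
                            artifact(config, "subreddit_distribution.csv"),
                            config)
  write_csv_with_provenance(summary$doses$sequence_dist,
                            artifact(config, "dose_sequence_distribution.csv"),
                            config)
  write_csv_with_provenance(summary$doses$final_dose_dist,
                            artifact(config, "final_dose_distribution.csv"),
                            config)
  inform(sprintf("summarize: %d sampled, cessation %.1f%%", summary$n_sampled,
                 summary$pct_cessation))
  list(summary_json = p_json, summary_txt = p_txt, summary = summary)
}
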