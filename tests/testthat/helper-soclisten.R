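# fixtures are built in code; nothing binary ships with the tests

default_criteria <- screening_criteria()
test_obf <- obfuscation_config("testthat-salt")

# a tiny raw corpus: 2 comments + 1 submission, all screenable
tiny_raw_corpus <- function() {
  tibble::tibble(
    id = c("aaa111", "bbb222", "ccc333"),
    author = c("alice", "bob", "alice"),
    created_utc = c(1519862400, 1600000000, 1650000000),  # 2018-03-01, 2020, 2022
    subreddit = c("Sublocade", "sublocade", "opiates"),
    title = c(NA, NA, "Last shot"),
    selftext = c(NA, NA, "tapering off sublocade now"),
    body = c("Starting sublocade, will taper later", "time to stop sublocades", NA)
  )
}

write_jsonl_corpus <- function(records, path = tempfile(fileext = ".jsonl")) {
  write_records(records, path)
  path
}

tiny_normalized <- function() {
  normalize_records(tiny_raw_corpus(), test_obf)
}

# independent naive substring scan: checks every keyword at every position
naive_substring_match <- function(text, keywords) {
  text <- tolower(text)
  vapply(text, function(t) {
    n <- nchar(t)
    any(vapply(keywords, function(kw) {
      k <- nchar(kw)
      if (k > n) return(FALSE)
      starts <- seq_len(n - k + 1)
      any(substring(t, starts, starts + k - 1) == kw)
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

# brute-force variant enumeration: all strings over `alphabet` of length
# |term| +/- max_distance, kept if adist() <= max_distance
brute_force_variants <- function(term, max_distance, alphabet) {
  lens <- max(0, nchar(term) - max_distance):(nchar(term) + max_distance)
  cands <- unlist(lapply(lens, function(L) {
    if (L == 0) return("")
    grid <- do.call(expand.grid, rep(list(alphabet), L))
    apply(grid, 1, paste, collapse = "")
  }))
  cands <- unique(cands)
  sort(cands[as.vector(utils::adist(term, cands)) <= max_distance])
}

# random sentences over a clean alphabet, with keywords planted in a fraction
random_texts <- function(n, keywords, p_plant = 0.3, seed = 1) {
  withr::with_seed(seed, {
    base <- vapply(seq_len(n), function(i) {
      paste(sample(c(letters, " "), sample(20:60, 1), replace = TRUE),
            collapse = "")
    }, character(1))
    plant <- runif(n) < p_plant
    kw <- sample(keywords, n, replace = TRUE)
    ifelse(plant, paste(base, kw, base), base)
  })
}
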