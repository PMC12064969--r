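---
title: "Screening methodology and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening methodology and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soclisten)
```

`soclisten` operationalizes a social-listening study of treatment cessation
with extended-release injectable buprenorphine (BUP-XR): screen a Reddit-style
corpus with explicit inclusion criteria, protect contributor privacy, draw a
seeded coding sample, validate the manual annotations, and describe the
result. This vignette records the methodology and, more importantly, the
design decisions — where the procedure was genuinely open, what we chose, and
why.

## The screening model

Screening is a fixed four-gate funnel. Gates are conjunctive and ordered;
the order matters because deduplication changes the denominator of every
later stage.

1. **Referent gate.** Two *parallel* criteria, OR-combined: (a) the record's
   free text contains a case-insensitive substring match to one of 20
   explicit search strings — the brand spelling plus 19 misspellings, all
   within Levenshtein distance 1 of `"sublocade"` — or (b) the record was
   created in the target subreddit. The parallel design reflects the two
   ways relevant records arise: brand mentions anywhere on the platform, and
   context-relevant discussion inside the dedicated community that may never
   name the drug.
2. **Deduplication** on the obfuscated record id, first occurrence kept.
3. **Cessation gate.** Substring match to one of eight cessation keywords
   (*taper, stop, final, quit, last, reduce, decrease, discontinue*).
4. **Date window**, inclusive on both ends.

### Substring versus token matching

The inclusion criteria are phrased as fields that *contain* matches, so
substring semantics are the default (`match_mode = "substring_list"`,
`match_cessation(mode = "substring")`). Substring matching has a known
false-positive surface — "at last I feel normal" passes the cessation gate —
which we keep deliberately: fidelity to the stated criteria first. Two
stricter variants are provided for sensitivity analysis and are surfaced in
the attrition table when used: a whole-token cessation mode, and a
`generative_token` term mode that matches any delimited token within
`max_distance` of the seed term rather than consulting the fixed list.

### Fixed list versus generated neighbourhood

The distance-1 rule is operationalized as the explicit 20-string list
(`sublocade_variants()`), not as the full generated neighbourhood: the list
is the citable, auditable artifact. `enumerate_variants()` constructs the
exact edit-distance ball when the generative analysis is wanted; for a
9-letter word with no repeated letters the distance-1 ball over `a–z`
contains 486 distinct strings (1 identity + 9 deletions + 225 substitutions
+ 251 distinct insertions — insertions double-count once per position where
the inserted letter equals its neighbour). The constructor refuses variant
lists that violate the declared distance bound, so configuration drift is
caught at build time.

### Case folding and timezones

Case folding is plain ASCII lowercasing — every keyword list is ASCII, and
locale-dependent folds (e.g. Turkish dotless-i) would make matching
irreproducible across machines. Epoch timestamps are interpreted in UTC,
the only choice that makes date-window boundaries reproducible; submissions'
`title` and `selftext` are joined with a single newline, which preserves
both fields while keeping within-field substring matches intact (a match can
never span the two fields).

## Privacy

Identifiers are replaced by `base36(first 64 bits of SHA-256(salt ⟂ value))`
at a default 10 base-36 digits. The construction is deterministic per salt
(so equality structure — records by one author — survives), one-way, and
emits the base-36 alphabet expected of such identifiers. The hash and token
length are package decisions: no external specification of the original
study's construction exists, so the exact token values are not, and cannot
be, comparable to any prior dataset. An empty salt is a configuration error,
refused loudly.

Redaction removes emails, URLs, phone numbers and `u/`-username mentions,
in that order (URLs first, so `reddit.com/u/...` paths cannot leave a
username fragment behind). Placeholders never match any rule, making
redaction idempotent. The rule set is a floor: `redaction_rules(extra =)`
appends study-specific classes.

## Sampling

`draw_sample()` selects `round_half_up(n × fraction)` records uniformly
without replacement, preserving input order, under a mandatory seed that is
echoed into every output. Half-up rounding is the documented tie-break for
odd `n` (at the study's scale, 6082 × 0.5 = 3041 exactly, so the rule is
unconstrained there). The original study's seed is unrecoverable; ours is
mandatory precisely so that no future sample of ours is.

## The codebook and validation

Annotations carry one column per codebook field (snake_case), plus
`cessation_timing` (retrospective vs planned): the construct split is
reported in study results, so the schema must carry it even though the
field table itself lacks the column. Validation severities: logical
contradictions (a coded cessation without a coded drug referent; a course
whose length disagrees with the dose count; durations ordered
Sublocade > buprenorphine > any-MOUD) are **errors**; in-range but
implausible doses are **warnings**. Dose bounds are a package decision — no
bound is externally specified beyond the milligram unit — set to (0, 300] mg
(300 mg is the marketed maximum; partial doses are discussed by patients, so
any positive integer in range validates, with values off the 50 mg grid
flagged as oddities).

## Descriptive statistics

Percentages are `round_half_up(100 · a/b, 1)`; half-up at one decimal
matches the presentation convention of descriptive tables in this field
(base R `round()` is half-to-even and would disagree on ties). Reported SDs
use the sample (n − 1) formula. The IQR is Q3 − Q1 with type-7
linear-interpolation quantiles — one defensible convention, fixed and
documented. Degenerate inputs are defined, not exceptional: a single-author
corpus reports SD 0 with `sd_undefined = TRUE`; a zero denominator yields
`NA` percent; an empty corpus yields zero counts.

One published figure is deliberately not reproduced as a ratio: the coded
referent count is printed alongside a percentage whose denominator cannot be
identified from the published numbers (2692 / 3041 = 88.5%, not the printed
97.4%). `summary_report()` therefore always reports the *computed* percent
of the coded sample with its numerator and denominator carried in the
output, and the unexplained figure is used nowhere as a target.

## The synthetic corpus: what it does and does not emulate

`generate_corpus()` exists because the archival Reddit source is no longer
publicly retrievable. Its defaults **are** the study conditions:

| parameter | default | source |
|---|---|---|
| records/author mean, SD, max | 4.5, 13.6, 275 | reported per-author moments |
| target-subreddit share | 0.976 | reported |
| cessation among referents | 0.438 | reported |
| withdrawal among cessation | 0.087 | reported |
| retrospective among cessation | 0.828 | reported |
| craving among cessation | 1/1179 | reported single record |
| n_authors | 1100 | ≈5000 records at the mean rate |
| term-mention probability | 0.95 | package choice: referent-rich corpus |
| cessation-keyword probability | 0.9 | package choice: keyword-rich corpus |
| out-of-window fraction | 0.05 | package choice: exercises the date gate |
| injected duplicates | 25 | package choice: exercises deduplication |

Records per author are 1 + a negative binomial with the dispersion solved
from the target mean and SD, truncated at 275 — the reported moments
constrain but do not identify a family; a shifted negative binomial is the
standard overdispersed count model. Texts are template sentences embedding
the planted variant/keyword/decoy strings; the generator *proves* its own
ground truth at build time by rescanning every text (a record not flagged
as mentioning the term is guaranteed to contain no variant substring). Decoy
strings are distance-2 from the seed and verified never to contain any
explicit variant as a substring.

What the generator does **not** emulate: natural language. Template
sentences have none of the ambiguity, slang, sarcasm or context-dependence
of real posts, so green tests demonstrate that the *lexical machinery* is
correct — gates match exactly what they claim to match, stages compose in
the right order, statistics are computed as defined — and nothing about how
well the criteria capture real-world meaning. Construct prevalences are
planted at the reported rates, so recovered proportions validate the
plumbing, not the study's substantive findings.

## Verification strategy and problem sizes

Every matcher is checked against an independent oracle: `edit_distance()`
against `utils::adist()` on random strings, `enumerate_variants()` against
exhaustive generate-and-filter brute force on alphabets of up to four
letters, substring screening against a naive all-positions scan on 10,000
random planted texts. Prevalence recovery is tested on a default-sized
corpus (~5000 records) within three binomial standard errors of the planted
values; end-to-end determinism is asserted byte-for-byte on two full runs at
150 authors. These sizes are the package's chosen trade-off between
statistical resolution and a test suite that stays fast enough to run on
every change.

## Known limitations

- Substring cessation matching over-includes (quantified, not corrected);
  the token mode under-includes morphological variants ("tapering").
- Author-level statistics treat accounts as people; one person with several
  accounts inflates author counts (inherited caveat, documented not
  corrected).
- Redaction rules are regex floors; unusual PII formats (spelled-out phone
  numbers, obfuscated emails) pass through.
- The obfuscation token is 64 bits truncated; collision probability at
  10^5 identifiers is ~3×10⁻¹⁰ — negligible for corpus work, not a
  cryptographic commitment.
- `screen_corpus()` is single-threaded and holds the corpus in memory;
  it is sized for desk-scale corpora (10⁴–10⁶ records), not platform dumps.
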