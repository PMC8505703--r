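---
title: "Measuring negative perception in tweet streams: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring negative perception in tweet streams: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(negindex)
```

## The instrument

`negindex` measures the negative perception carried by a stream of short
social-media posts with a deliberately simple statistic. A curated lexicon
of words that are negative in essentially any context is matched, token by
token, against each day's tweets. With

- *T(d)*: the number of tweets on UTC day *d* (after filtering), and
- *N(d)*: the total number of lexicon-word occurrences in those tweets,
  counted with multiplicity,

the daily **negative frequency index** is *I(d) = N(d) / T(d)* —
occurrences per tweet. The normalisation makes days with different posting
volumes comparable: doubling every tweet doubles both counts and leaves the
index unchanged (a property the test suite asserts exactly).

The method's assumptions are worth stating plainly:

- **A word's valence is context-free.** The lexicon contains only words
  judged unambiguously negative, precisely so that no per-word sentiment
  score, negation handling, or phrase model is needed. The price is that
  "living in a hotel is not so bad" scores 1: the counter is blind to
  negation, irony and sarcasm. This is a property of the instrument; the
  package pins it down with a regression test rather than "fixing" it,
  because correcting it would change the statistic being computed.
- **Counting is exact-token and case-insensitive.** "mad" never matches
  inside "made"; misspellings are not matched; "worried" and "worry" are
  distinct entries. There is no stemming, by design — the lexicon lists the
  inflected forms it wants.
- **A day is a UTC day.** The stream is global, no local timezone is
  privileged, and daily aggregation needs one fixed boundary.

## The lexicon

The packaged default list has 110 printed entries, of which 108 are unique
(two words appear twice in the printed source and are collapsed at load
time — occurrence counting must not double-count a token because the
dictionary listed it twice; the original token count is kept as metadata).
All entries are single lowercase tokens. User lexicons load from plain text
(one word per line, commas also accepted, `#` comments); multi-word entries
are rejected with an error, since a single-token matcher could never fire on
them and silence would be worse.

## Tokenization

No standard tokenizer is implied by word counting, so the package defines
one and isolates it behind `tokenize_text()` so alternatives can be swapped:
case-fold; drop URLs and @-mentions entirely; split on any character that is
not a letter, digit or apostrophe (which also strips `#` from hashtags while
keeping the tag word); strip leading/trailing apostrophes; drop empties.
Apostrophes stay word-internal so "don't" remains one token rather than
shedding spurious "don" and "t" tokens. These rules are one defensible
realisation; the test suite pins them against an independently written
character-level oracle on a thousand seeded messy tweets (URLs, hashtags,
mentions, repeated words), requiring exact agreement.

## Corpus handling

Corpora are newline-delimited JSON (`id`, `timestamp`, `lang`, `text`);
timestamps may be ISO-8601 or epoch seconds and are normalised to UTC on
read. Malformed lines are counted and skipped — real dumps always contain
junk — but a file that is more than half malformed raises an error as
probably being the wrong format. Filters (`filter_language()`, default
`"en"`; `filter_retweets()`, dropping the literal `"RT @"` prefix;
`filter_keywords()`, matching on scored tokens) only ever subset the stream
and commute with each other. *T(d)* is defined as the post-filter tweet
count, consistent with analysing an English-language stream. For corpora too
large to hold in memory, `aggregate_daily_file()` accumulates the daily
counts chunk by chunk, so peak memory is governed by the chunk size; the
suite verifies the chunked and in-memory paths produce identical series.
Deduplication of identical texts (spam) is not implemented — users with
spam-heavy streams should deduplicate upstream.

## The daily series and its storage

Integer counts are the source of truth: the stored double `index` is always
re-derivable from `negative_words / total_tweets`, and the CSV reader warns
when a stored index deviates from the counts by more than 1e-12 (counts
win). Days with *T(d) = 0* are present but flagged `missing` — an undefined
index is represented, never imputed and never silently zero — and missing
days are dropped from every downstream fit rather than interpolated, since
no principled imputation rule exists for an unobserved day.

## Trend characterisation

- **Rolling mean** (`rolling_mean()`): centred, default 7 days to damp
  weekly posting seasonality; odd windows only, shrunken at the endpoints,
  missing days contribute nothing.
- **Linear trend** (`fit_linear_trend()`): ordinary least squares of
  *I(d)* on the integer day offset from the window start, solved by the
  closed-form normal equations (this one fit is implemented in-repo rather
  than through `lm()` so that the estimator is fully specified by the
  package; the suite cross-checks it against both a matrix-algebra oracle
  and `lm()` to 1e-10). The x-origin at the window start keeps the
  intercept interpretable as the fitted index on the first day; the slope is
  invariant to translating all dates, which is also asserted. The 95% CI
  uses the t distribution on n − 2 degrees of freedom. At least 3
  non-missing days are required.
- **Band check** (`range_check()`): extrema and the fraction of non-missing
  days inside a stated inclusive band, for plateau claims of the form "the
  index stays within [0.15, 0.18]".
- **Window contrast** (`compare_windows()`): the source analysis performs no
  formal test, so the package adds the least parametric one available — a
  seeded permutation test of the difference in window means (default 10,000
  permutations, two-sided, with the +1 correction so p is never exactly 0).
  Windows must be disjoint with ≥3 non-missing days each. The suite checks
  the p-value against exhaustive enumeration at small n and its uniformity
  under the null.
- **External series** (`align_and_correlate()`): two-column `date,value`
  CSVs; the external series may be shifted by a lag, is inner-joined on
  date, and Pearson correlation is reported with the pair count. Cumulative
  series at non-daily cadence (vaccination share) may be forward-filled up
  to 6 days; values are never back-filled, and incidence series such as
  daily deaths should not be filled at all. Correlation here is read as
  association only — the package makes no causal claim.

## The synthetic generator

`generate_corpus()` exists so the whole pipeline is testable without
platform access. It emulates the statistical structure the analysis
assumes: daily volumes Poisson around `tweets_per_day`; per-tweet
negative-token counts Poisson with a day-varying intensity λ(d); negative
tokens drawn uniformly from the lexicon; filler tokens drawn from a
pronounceable-nonsense neutral vocabulary whose disjointness from the
lexicon is asserted at construction (a real-word vocabulary would risk
accidental collisions); a `lang_mix` fraction of tweets tagged non-English
to exercise the language filter. λ(d) is piecewise — a plateau, an optional
linear decline from a start date, and optional multiplicative spikes for
short news-driven bursts. The Poisson (rather than Bernoulli) per-tweet
draw allows several occurrences in one tweet, matching occurrence-counting
semantics, and makes E[I(d)] = λ(d) exactly, so parameter-recovery tests
are clean.

The generator's defaults are the study conditions the pipeline is meant to
detect: a plateau of 0.165 (the middle of the [0.15, 0.18] band), a decline
of −5e-4 per day, 5,000 tweets per day, and a mean tweet length of 12
tokens (a realistic token count for short posts). All randomness flows from
one seed drawn sequentially day by day; a fixed profile yields
byte-identical output files, which the suite checks by hashing.

Two things the generator records make validation exact rather than
statistical: the ground-truth file stores the *realized* per-day counts
(not just expectations), and `ground_truth_check()` re-runs the real
pipeline on the corpus and demands exact equality of N(d) and T(d) on every
day — any tokenizer leakage between neutral text and the lexicon would
surface immediately.

For large recovery experiments, `simulate_daily_series()` draws the daily
counts directly from the same model: T(d) ~ Poisson of the English volume
and N(d) | T(d) ~ Poisson(T(d)·λ(d)), the exact distribution of the daily
sums under the corpus model, since token placement inside a tweet cannot
change a daily sum. Writing millions of tweet texts to disk adds nothing to
a test of the trend estimator, so the 20-replicate slope-recovery check runs
at its full study conditions (60 plateau days, 120 decline days, 5,000
tweets/day) through this path, while corpus-level exactness is established
separately on a 100,000-tweet generated corpus. A unit test confirms the
two paths agree distributionally on a small shared profile.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real streams: linguistic realism (grammar, negation,
irony), hashtag/URL frequencies beyond what the tokenizer tests need, spam
and bot subpopulations, topic drift in what the lexicon's words mean, and
any dependence between volume and negativity. Recovery results validate the
pipeline's arithmetic and estimators, not the construct validity of word
counting as a measure of emotion.

## Interfaces and configuration

`run_simulate()`, `run_score()` and `run_trend()` wrap the pipeline for
scripted use, and a thin `negindex` Rscript (in `inst/exec/`) exposes them
as shell subcommands with exit codes 0/1/2 (ok / runtime error / usage
error). Configuration files are YAML key-value documents — a plain,
human-editable standard format with a reader available in R — and
command-line flags override file values. The trend step writes a
machine-readable JSON report and static figures (daily counts; index with
the fitted line; index against a scaled external series). The regression
window is a user parameter: analyses of a vaccination-era decline would
typically fit from the campaign's start, and the report records whatever
window was used.

## Numerical and degenerate-input choices

- Index consistency tolerance on CSV read: 1e-12 (counts prevail).
- OLS is exact closed-form; no iterative fitting anywhere in the package.
- T(d) = 0 → `NA` index, flagged, excluded from fits; an empty corpus
  yields an empty series with a warning, not an error.
- Fits require ≥3 points; permutation windows ≥3 non-missing days each and
  disjointness is enforced.
- Permutation p-values use (1 + b) / (B + 1), so they are never zero.
- The problem sizes used by the test suite and acceptance script (e.g. a
  100,000-tweet corpus for conservation, 20 replicates at 5,000 tweets/day
  for recovery) were chosen as the smallest scales at which the checked
  properties are sharp; they are stated in the tests themselves.

## Known limitations

The index inherits every limitation of context-free word counting: a small
vocabulary, blindness to misspellings, negation, irony and sarcasm, and
sensitivity to who is posting (activist subpopulations with strong emotional
tone can skew it). Conclusions drawn from it describe the posting
population, not the general population. The package's correlation tools
quantify co-movement with external series only; establishing why an index
moves requires evidence beyond this instrument.
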