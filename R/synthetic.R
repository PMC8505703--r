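#' Define a synthetic corpus profile
#'
#' A profile fixes the statistical structure of a generated tweet stream:
#' daily volumes are Poisson with mean `tweets_per_day`; each tweet's
#' negative-token count is Poisson with the day's intensity lambda(d), so
#' the expected index E[I(d)] equals lambda(d) exactly (a Poisson rather
#' than Bernoulli draw allows more than one occurrence per tweet, matching
#' occurrence-counting semantics). lambda(d) is piecewise: a plateau
#' value until `decline_start`, then a linear change of `decline_slope`
#' per day; optional spikes multiply lambda over short date ranges,
#' emulating news-driven bursts of negativity. A fraction `lang_mix` of
#' tweets is tagged with a non-English language code and is excluded from
#' the ground truth, since the pipeline's English filter removes them.
#'
#' The defaults mirror the study conditions the pipeline is meant to
#' recover: a plateau of 0.165 (the middle of the reported [0.15, 0.18]
#' band) and, when a decline is requested, a slope of -5e-4 per day.
#'
#' @param start,end first and last day of the corpus (Date or string).
#' @param tweets_per_day mean daily tweet volume.
#' @param plateau plateau value of lambda(d), occurrences per tweet.
#' @param decline_start date the linear decline begins (`NULL` = never).
#' @param decline_slope change in lambda per day after `decline_start`.
#' @param spikes list of `list(start =, end =, factor =)` multiplicative
#'   spikes on lambda.
#' @param tweet_length mean neutral tokens per tweet (Poisson, min 1).
#' @param neutral_vocab_size size of the neutral vocabulary.
#' @param lang_mix fraction of tweets tagged non-English.
#' @param seed integer seed; the same profile and seed give byte-identical
#'   output files.
#' @return A `synthetic_profile` list.
#' @export
synthetic_profile <- function(start, end,
                              tweets_per_day = 5000,
                              plateau = 0.165,
                              decline_start = NULL,
                              decline_slope = -5e-4,
                              spikes = list(),
                              tweet_length = 12,
                              neutral_vocab_size = 500L,
                              lang_mix = 0,
                              seed = 1L) {
  start <- as.Date(start)
  end <- as.Date(end)
  stopifnot(start <= end, tweets_per_day > 0, plateau >= 0,
            tweet_length >= 1, lang_mix >= 0, lang_mix < 1)
  if (!is.null(decline_start)) decline_start <- as.Date(decline_start)
  prof <- structure(
    list(
      start = start, end = end,
      tweets_per_day = tweets_per_day,
      plateau = plateau,
      decline_start = decline_start,
      decline_slope = decline_slope,
      spikes = spikes,
      tweet_length = tweet_length,
      neutral_vocab_size = as.integer(neutral_vocab_size),
      lang_mix = lang_mix,
      seed = as.integer(seed)
    ),
    class = "synthetic_profile"
  )
  lam <- lambda_profile(prof)
  if (any(lam < 0)) {
    stop("profile yields negative lambda(d); shorten the decline or flatten the slope",
         call. = FALSE)
  }
  prof
}

#' Per-day negativity intensity lambda(d) of a profile
#'
#' @param profile a [synthetic_profile()].
#' @return Named numeric vector of lambda values, one per day of the
#'   profile's date range.
#' @export
lambda_profile <- function(profile) {
  days <- seq(profile$start, profile$end, by = "day")
  lam <- rep(profile$plateau, length(days))
  if (!is.null(profile$decline_start)) {
    off <- as.numeric(days - profile$decline_start)
    lam <- ifelse(off > 0, profile$plateau + profile$decline_slope * off, lam)
  }
  for (sp in profile$spikes) {
    in_sp <- days >= as.Date(sp$start) & days <= as.Date(sp$end)
    lam[in_sp] <- lam[in_sp] * sp$factor
  }
  names(lam) <- format(days)
  lam
}

#' Build a neutral vocabulary disjoint from a lexicon
#'
#' Pronounceable nonsense words assembled from consonant-vowel syllables,
#' enumerated deterministically and checked against the lexicon (a real
#' word list would risk accidental collisions). Disjointness is asserted,
#' not assumed.
#'
#' @param n vocabulary size.
#' @param lexicon a [neg_lexicon()] the vocabulary must avoid.
#' @return Character vector of `n` distinct words, none in the lexicon.
#' @export
neutral_vocabulary <- function(n, lexicon) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vows <- c("a", "e", "i", "o", "u")
  syll <- as.vector(outer(cons, vows, paste0))
  words <- character(0)
  len <- 2L
  while (length(words) < n) {
    grid <- do.call(expand.grid, rep(list(syll), len))
    cand <- do.call(paste0, grid)
    cand <- cand[!cand %in% lexicon$words]
    words <- unique(c(words, cand))
    len <- len + 1L
    if (len > 4L) break
  }
  words <- utils::head(words, n)
  stopifnot(length(words) == n, !any(words %in% lexicon$words))
  words
}

#' Generate a synthetic tweet corpus with ground truth
#'
#' Writes a JSONL corpus and a CSV ground-truth file recording, for each
#' day, the true intensity lambda(d) and the realized counts the pipeline
#' must reproduce exactly: `realized_T` (English tweets written) and
#' `realized_N` (negative tokens placed in them). Non-English tweets are
#' generated but excluded from the truth, since the analysis pipeline
#' filters them out. All randomness flows from the profile's single seed,
#' drawn sequentially day by day, so a fixed profile gives byte-identical
#' files across runs.
#'
#' @param profile a [synthetic_profile()].
#' @param lexicon a [neg_lexicon()]; negative tokens are drawn uniformly
#'   from it.
#' @param corpus_path output JSONL path.
#' @param truth_path output ground-truth CSV path (`day,lambda,realized_T,
#'   realized_N`).
#' @return Invisible list with the two paths and the truth tibble.
#' @export
generate_corpus <- function(profile, lexicon, corpus_path, truth_path) {
  stopifnot(inherits(profile, "synthetic_profile"), inherits(lexicon, "neg_lexicon"))
  vocab <- neutral_vocabulary(profile$neutral_vocab_size, lexicon)
  lam <- lambda_profile(profile)
  days <- seq(profile$start, profile$end, by = "day")
  set.seed(profile$seed)
  con <- file(corpus_path, "wb")
  on.exit(close(con))
  truth <- vector("list", length(days))
  for (i in seq_along(days)) {
    d <- days[i]
    t_d <- stats::rpois(1, profile$tweets_per_day)
    if (t_d == 0L) {
      truth[[i]] <- tibble::tibble(
        day = format(d), lambda = lam[i], realized_T = 0L, realized_N = 0L
      )
      next
    }
    k <- stats::rpois(t_d, lam[i])
    n_neutral <- pmax(1L, stats::rpois(t_d, profile$tweet_length))
    is_en <- stats::runif(t_d) >= profile$lang_mix
    texts <- vapply(seq_len(t_d), function(j) {
      toks <- c(
        if (k[j] > 0L) sample(lexicon$words, k[j], replace = TRUE),
        sample(vocab, n_neutral[j], replace = TRUE)
      )
      paste(sample(toks), collapse = " ")
    }, character(1))
    secs <- sort(sample.int(86400L, t_d, replace = TRUE)) - 1L
    ts <- format(
      as.POSIXct(as.numeric(as.POSIXct(d, tz = "UTC")) + secs,
                 origin = "1970-01-01", tz = "UTC"),
      "%Y-%m-%dT%H:%M:%SZ"
    )
    ids <- sprintf("%s-%06d", format(d, "%Y%m%d"), seq_len(t_d))
    langs <- ifelse(is_en, "en", "es")
    writeLines(corpus_json_lines(ids, ts, langs, texts), con, useBytes = TRUE)
    truth[[i]] <- tibble::tibble(
      day = format(d), lambda = lam[i],
      realized_T = sum(is_en), realized_N = sum(k[is_en])
    )
  }
  truth <- dplyr::bind_rows(truth)
  utils::write.csv(truth, truth_path, row.names = FALSE, quote = FALSE)
  invisible(list(corpus_path = corpus_path, truth_path = truth_path, truth = truth))
}

#' Simulate the daily count series of a profile directly
#'
#' Draws the realized daily counts (T(d), N(d)) from the same model as
#' [generate_corpus()] without materialising tweet text: T(d) is Poisson
#' with mean `tweets_per_day * (1 - lang_mix)` (the English stream) and
#' N(d) given T(d) is Poisson with mean `T(d) * lambda(d)` — the sum of
#' T(d) independent Poisson(lambda) per-tweet counts. Token placement
#' inside a tweet cannot change the daily sums, so the resulting series
#' has the same distribution as running the full pipeline on a generated
#' corpus; use this for large parameter-recovery experiments where
#' writing millions of tweets would be pointless.
#'
#' @param profile a [synthetic_profile()].
#' @return An `index_series` tibble, with the true `lambda` attached as
#'   attribute `lambda`.
#' @export
simulate_daily_series <- function(profile) {
  stopifnot(inherits(profile, "synthetic_profile"))
  lam <- lambda_profile(profile)
  days <- seq(profile$start, profile$end, by = "day")
  set.seed(profile$seed)
  t_d <- stats::rpois(length(days), profile$tweets_per_day * (1 - profile$lang_mix))
  n_d <- stats::rpois(length(days), t_d * lam)
  out <- new_index_series(days, t_d, n_d)
  attr(out, "lambda") <- unname(lam)
  out
}

#' Verify pipeline output against generator ground truth
#'
#' Re-runs the real pipeline (English filter, tokenizer, lexicon counting,
#' daily aggregation) on a generated corpus and checks that the realized
#' N(d) and T(d) match the generator's bookkeeping exactly on every day.
#' Any mismatch — a day missing, a count off by one — is reported.
#'
#' @param corpus_path JSONL corpus from [generate_corpus()].
#' @param truth_path ground-truth CSV from the same call.
#' @param lexicon the same [neg_lexicon()] used at generation.
#' @return List with `ok` (logical) and `mismatches` (tibble of days where
#'   pipeline and truth disagree; empty when `ok`).
#' @export
ground_truth_check <- function(corpus_path, truth_path, lexicon) {
  corpus <- read_corpus(corpus_path, quiet = TRUE)
  corpus <- filter_language(corpus, "en", quiet = TRUE)
  series <- suppressWarnings(aggregate_daily(corpus, lexicon))
  truth <- utils::read.csv(truth_path, stringsAsFactors = FALSE,
                           colClasses = c(day = "character"))
  merged <- dplyr::full_join(
    tibble::tibble(day = format(series$day),
                   pipe_T = series$total_tweets, pipe_N = series$negative_words),
    tibble::tibble(day = truth$day,
                   true_T = truth$realized_T, true_N = truth$realized_N),
    by = "day"
  )
  merged[is.na(merged)] <- 0L
  bad <- merged$pipe_T != merged$true_T | merged$pipe_N != merged$true_N
  list(ok = !any(bad), mismatches = merged[bad, , drop = FALSE])
}
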