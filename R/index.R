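#' The daily negative frequency index
#'
#' The index for day d is I(d) = N(d) / T(d), where N(d) is the total
#' number of negative-word occurrences across the day's tweets and T(d)
#' the number of tweets posted that day. Normalising by volume makes days
#' with different posting activity comparable: duplicating every tweet
#' doubles both counts and leaves I(d) unchanged.
#'
#' Vectorised. Days with no tweets (T = 0) get `NA` — an undefined index,
#' never zero and never an error at series level.
#'
#' @param n negative-word occurrence count(s), non-negative.
#' @param t total tweet count(s), non-negative.
#' @return Numeric vector: `n / t`, with `NA` where `t == 0`.
#' @export
#' @examples
#' negative_frequency_index(18, 100) # 0.18
negative_frequency_index <- function(n, t) {
  if (any(n < 0, na.rm = TRUE) || any(t < 0, na.rm = TRUE)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  out <- ifelse(t > 0, n / t, NA_real_)
  as.numeric(out)
}

#' Construct a daily index series from counts
#'
#' Builds a validated `index_series` tibble from per-day integer counts:
#' days are sorted, gaps inside the range are padded with zero-count rows
#' flagged `missing`, and the index is derived from the counts (the
#' integers are the source of truth; the stored double is always
#' re-derivable from them).
#'
#' @param day vector of dates (one per observed day, no duplicates).
#' @param total_tweets integer tweet counts T(d).
#' @param negative_words integer negative-occurrence counts N(d).
#' @return An `index_series` tibble with columns `day`, `total_tweets`,
#'   `negative_words`, `index`, `missing`.
#' @export
new_index_series <- function(day, total_tweets, negative_words) {
  stopifnot(length(day) == length(total_tweets),
            length(day) == length(negative_words))
  out <- tibble::tibble(
    day = as.Date(day),
    total_tweets = as.integer(total_tweets),
    negative_words = as.integer(negative_words)
  )
  out <- out[order(out$day), , drop = FALSE]
  if (nrow(out) > 0L) {
    stopifnot(!anyDuplicated(out$day))
    full <- seq(min(out$day), max(out$day), by = "day")
    if (length(full) > nrow(out)) {
      pad <- tibble::tibble(
        day = full[!full %in% out$day],
        total_tweets = 0L, negative_words = 0L
      )
      out <- dplyr::arrange(dplyr::bind_rows(out, pad), .data$day)
    }
  }
  out$index <- negative_frequency_index(out$negative_words, out$total_tweets)
  out$missing <- out$total_tweets == 0L
  class(out) <- c("index_series", class(tibble::tibble()))
  out
}

#' Aggregate a corpus into the daily index series
#'
#' Scores every tweet against the lexicon and sums per UTC calendar day:
#' T(d) = number of tweets, N(d) = total negative-word occurrences,
#' I(d) = N(d)/T(d). Day boundaries are UTC — the stream is global and no
#' single local timezone is privileged. Days inside the observed range
#' with no tweets are present in the output but flagged `missing` (and
#' excluded from trend fits downstream), never imputed.
#'
#' @param corpus corpus tibble (apply filters such as [filter_language()]
#'   first; T(d) counts post-filter tweets).
#' @param lexicon a [neg_lexicon()].
#' @return An `index_series` tibble with columns `day`, `total_tweets`,
#'   `negative_words`, `index`, `missing`.
#' @export
#' @examples
#' lex <- default_lexicon()
#' corpus <- tibble::tibble(
#'   id = "1", timestamp = as.POSIXct("2020-03-01 12:00:00", tz = "UTC"),
#'   lang = "en", text = "fear"
#' )
#' aggregate_daily(corpus, lex)
aggregate_daily <- function(corpus, lexicon) {
  if (nrow(corpus) == 0L) {
    warning("empty corpus: returning empty series", call. = FALSE)
    return(new_index_series(as.Date(character()), integer(), integer()))
  }
  scores <- score_tweets(corpus, lexicon)
  day <- as.Date(corpus$timestamp, tz = "UTC")
  agg <- dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(day = day, nc = scores$negative_count), .data$day
    ),
    total_tweets = dplyr::n(),
    negative_words = sum(.data$nc),
    .groups = "drop"
  )
  new_index_series(agg$day, agg$total_tweets, agg$negative_words)
}

#' Aggregate a large JSONL corpus file in bounded memory
#'
#' Streams the file in chunks of `chunk_size` lines, applying the language
#' (and optionally retweet) filter and accumulating per-day counts, so
#' peak memory is governed by the chunk size rather than the corpus
#' length. Produces exactly the same series as
#' `aggregate_daily(filter_language(read_corpus(path)), lexicon)`.
#'
#' @param path JSONL corpus file (optionally gzipped).
#' @param lexicon a [neg_lexicon()].
#' @param lang language code to keep, or `NULL` to keep all.
#' @param drop_retweets also drop "RT @" re-posts.
#' @param chunk_size lines per chunk.
#' @return An `index_series` tibble (see [aggregate_daily()]).
#' @export
aggregate_daily_file <- function(path, lexicon, lang = "en",
                                 drop_retweets = FALSE, chunk_size = 10000L) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  acc_t <- integer(0)
  acc_n <- integer(0)
  repeat {
    lines <- readLines(con, n = chunk_size, warn = FALSE)
    if (length(lines) == 0L) break
    chunk <- parse_corpus_lines(lines, quiet = TRUE, label = path)
    if (!is.null(lang)) chunk <- filter_language(chunk, lang, quiet = TRUE)
    if (drop_retweets) chunk <- filter_retweets(chunk, quiet = TRUE)
    if (nrow(chunk) == 0L) next
    scores <- score_tweets(chunk, lexicon)
    day <- format(as.Date(chunk$timestamp, tz = "UTC"))
    t_by <- tapply(rep(1L, nrow(chunk)), day, sum)
    n_by <- tapply(scores$negative_count, day, sum)
    for (d in names(t_by)) {
      acc_t[d] <- sum(acc_t[d], t_by[[d]], na.rm = TRUE)
      acc_n[d] <- sum(acc_n[d], n_by[[d]], na.rm = TRUE)
    }
  }
  if (length(acc_t) == 0L) {
    warning("no tweets survived filters: returning empty series", call. = FALSE)
    return(new_index_series(as.Date(character()), integer(), integer()))
  }
  new_index_series(as.Date(names(acc_t)), unname(acc_t), unname(acc_n))
}

#' Read and write daily index series as CSV
#'
#' Format: header `day,total_tweets,negative_words,index`, ISO dates, one
#' row per day. The integer counts are the source of truth; on read the
#' index is re-derived from them, and a stored index differing from N/T by
#' more than 1e-12 raises a validation warning. Days with `total_tweets`
#' 0 have an empty index field and come back flagged missing.
#'
#' @param series an `index_series` tibble.
#' @param path CSV path.
#' @return `write_series()`: `path`, invisibly. `read_series()`: an
#'   `index_series` tibble.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "index_series"))
  df <- data.frame(
    day = format(series$day),
    total_tweets = series$total_tweets,
    negative_words = series$negative_words,
    index = ifelse(is.na(series$index), "", sprintf("%.15g", series$index))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(day = "character"))
  stopifnot(all(c("day", "total_tweets", "negative_words", "index") %in% names(df)))
  stored <- suppressWarnings(as.numeric(df$index))
  derived <- negative_frequency_index(df$negative_words, df$total_tweets)
  off <- !is.na(stored) & !is.na(derived) & abs(stored - derived) > 1e-12
  if (any(off)) {
    warning(
      sprintf("stored index differs from N/T on %d row(s); counts take precedence",
              sum(off)),
      call. = FALSE
    )
  }
  new_index_series(as.Date(df$day), df$total_tweets, df$negative_words)
}

#' Export the raw daily count series
#'
#' Two-column CSV `day,negative_words` — the unnormalised N(d) series
#' (occurrences per day), as distinct from the volume-normalised index.
#'
#' @param series an `index_series` tibble.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(series, path) {
  stopifnot(inherits(series, "index_series"))
  utils::write.csv(
    data.frame(day = format(series$day), negative_words = series$negative_words),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
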