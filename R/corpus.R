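#' Read a tweet corpus from newline-delimited JSON
#'
#' Each line must be a JSON object with fields `id`, `timestamp`, `lang`
#' and `text`. Timestamps may be ISO-8601 strings or epoch seconds; both
#' are normalised to UTC. Malformed lines (bad JSON, missing fields,
#' unparseable timestamps) are counted and skipped with a warning rather
#' than aborting — large social-media dumps always contain junk lines —
#' but if more than half the lines are malformed the file is assumed to be
#' the wrong format and an error is raised. Gzip-compressed files
#' (`.gz`) are read transparently.
#'
#' @param path path to a JSONL (optionally gzipped) corpus file.
#' @param quiet suppress the skipped-lines warning.
#' @return A tibble with columns `id` (character), `timestamp` (POSIXct,
#'   UTC), `lang` (character), `text` (character), carrying attribute
#'   `skipped` (number of malformed lines dropped).
#' @export
read_corpus <- function(path, quiet = FALSE) {
  if (!file.exists(path)) {
    stop("corpus file not found: ", path, call. = FALSE)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  parse_corpus_lines(lines, quiet = quiet, label = path)
}

# Parse a character vector of JSONL records into a corpus tibble.
# Shared by read_corpus() and the chunked reader.
parse_corpus_lines <- function(lines, quiet = FALSE, label = "corpus") {
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n == 0L) {
    out <- tibble::tibble(
      id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
      lang = character(), text = character()
    )
    attr(out, "skipped") <- 0L
    return(out)
  }
  recs <- lapply(lines, function(l) {
    rec <- tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    if (is.null(rec) || !is.list(rec)) return(NULL)
    if (!all(c("id", "timestamp", "lang", "text") %in% names(rec))) return(NULL)
    ts <- parse_timestamp(rec$timestamp)
    if (is.na(ts)) return(NULL)
    list(
      id = as.character(rec$id), timestamp = ts,
      lang = as.character(rec$lang), text = as.character(rec$text)
    )
  })
  ok <- !vapply(recs, is.null, logical(1))
  skipped <- sum(!ok)
  if (skipped > n / 2) {
    stop(
      sprintf("%d of %d lines malformed in %s: likely not a JSONL corpus", skipped, n, label),
      call. = FALSE
    )
  }
  if (skipped > 0L && !quiet) {
    warning(sprintf("skipped %d malformed line(s) in %s", skipped, label), call. = FALSE)
  }
  recs <- recs[ok]
  out <- tibble::tibble(
    id = vapply(recs, `[[`, character(1), "id"),
    timestamp = as.POSIXct(
      vapply(recs, function(r) as.numeric(r$timestamp), numeric(1)),
      origin = "1970-01-01", tz = "UTC"
    ),
    lang = vapply(recs, `[[`, character(1), "lang"),
    text = vapply(recs, `[[`, character(1), "text")
  )
  attr(out, "skipped") <- skipped
  out
}

# ISO-8601 string or epoch seconds -> POSIXct UTC (NA if unparseable).
parse_timestamp <- function(x) {
  x <- x[1]
  if (is.numeric(x)) {
    return(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"))
  }
  x <- as.character(x)
  if (grepl("^-?[0-9]+(\\.[0-9]+)?$", x)) {
    return(as.POSIXct(as.numeric(x), origin = "1970-01-01", tz = "UTC"))
  }
  iso <- sub("Z$", "", sub("T", " ", x))
  out <- suppressWarnings(as.POSIXct(iso, tz = "UTC",
    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")))
  out
}

#' Write a tweet corpus to newline-delimited JSON
#'
#' @param corpus tibble with columns `id`, `timestamp`, `lang`, `text`.
#' @param path output path (`.gz` writes gzip).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(all(c("id", "timestamp", "lang", "text") %in% names(corpus)))
  lines <- corpus_json_lines(
    corpus$id,
    format(corpus$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    corpus$lang, corpus$text
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

# Deterministic JSONL serialisation (stable field order and escaping),
# so identical corpora are byte-identical on disk.
corpus_json_lines <- function(id, timestamp, lang, text) {
  esc <- function(s) {
    s <- gsub("\\", "\\\\", s, fixed = TRUE)
    s <- gsub("\"", "\\\"", s, fixed = TRUE)
    s <- gsub("\n", "\\n", s, fixed = TRUE)
    s <- gsub("\r", "\\r", s, fixed = TRUE)
    s <- gsub("\t", "\\t", s, fixed = TRUE)
    s
  }
  sprintf(
    '{"id":"%s","timestamp":"%s","lang":"%s","text":"%s"}',
    esc(id), esc(timestamp), esc(lang), esc(text)
  )
}

#' Corpus filters
#'
#' `filter_language()` keeps tweets whose `lang` equals the requested
#' ISO-639-1 code (default `"en"`, the study population).
#' `filter_retweets()` drops re-posts, identified by the conventional
#' literal prefix `"RT @"` after stripping leading whitespace; the
#' reference chatter dataset is already retweet-free, and this filter
#' re-establishes that property on arbitrary input. `filter_keywords()`
#' keeps tweets whose tokenized text (same tokenizer as the scoring step)
#' contains at least one of the given lowercase keywords, mirroring the
#' topic pre-filtering of the source dataset.
#'
#' All filters return a subset of their input; rows are never mutated.
#' Kept/dropped counts are reported via `message()`.
#'
#' @param corpus a corpus tibble (see [read_corpus()]).
#' @param lang 2-letter lowercase language code to keep.
#' @param keywords non-empty character vector of lowercase keywords.
#' @param quiet suppress the kept/dropped message.
#' @return The filtered corpus tibble.
#' @export
filter_language <- function(corpus, lang = "en", quiet = FALSE) {
  keep <- corpus$lang == lang
  if (!quiet) {
    message(sprintf("filter_language('%s'): kept %d, dropped %d",
                    lang, sum(keep), sum(!keep)))
  }
  corpus[keep, , drop = FALSE]
}

#' @rdname filter_language
#' @export
filter_retweets <- function(corpus, quiet = FALSE) {
  keep <- !startsWith(trimws(corpus$text, which = "left"), "RT @")
  if (!quiet) {
    message(sprintf("filter_retweets: kept %d, dropped %d", sum(keep), sum(!keep)))
  }
  corpus[keep, , drop = FALSE]
}

#' @rdname filter_language
#' @export
filter_keywords <- function(corpus, keywords, quiet = FALSE) {
  if (length(keywords) == 0L || !any(nzchar(keywords))) {
    stop("keywords must be a non-empty character vector", call. = FALSE)
  }
  keywords <- tolower(keywords)
  keep <- vapply(
    tokenize_text(corpus$text),
    function(toks) any(toks %in% keywords),
    logical(1)
  )
  if (length(keep) == 0L) keep <- logical(0)
  if (!quiet) {
    message(sprintf("filter_keywords: kept %d, dropped %d", sum(keep), sum(!keep)))
  }
  corpus[keep, , drop = FALSE]
}
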