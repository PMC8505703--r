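#' Negative-word lexicon objects
#'
#' A `neg_lexicon` is a deduplicated set of lowercase single-token words
#' treated as unambiguously negative. Matching against tweet tokens is
#' exact and case-insensitive; there is no stemming, so inflected forms
#' ("worry", "worried") must be listed separately if both are wanted.
#'
#' @param words character vector of words (will be case-folded, trimmed,
#'   deduplicated; order of first appearance is kept).
#' @param source_label free-text provenance string.
#' @param raw_token_count number of tokens in the source list before
#'   deduplication; defaults to `length(words)`.
#' @return A `neg_lexicon`: list with elements `words` (character),
#'   `source_label` (string) and `raw_token_count` (integer).
#' @export
#' @examples
#' lex <- neg_lexicon(c("Fear", "fear", "bad"), "demo")
#' lex$words
neg_lexicon <- function(words, source_label = "user", raw_token_count = length(words)) {
  stopifnot(is.character(words))
  words <- trimws(tolower(words))
  words <- words[nzchar(words)]
  if (length(words) == 0L) {
    stop("empty lexicon: no valid words", call. = FALSE)
  }
  bad <- grepl("\\s", words)
  if (any(bad)) {
    stop(
      "lexicon entries must be single tokens (no whitespace): ",
      paste(unique(words[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  dup <- duplicated(words)
  if (any(dup)) {
    warning(
      "duplicate lexicon entries collapsed: ",
      paste(unique(words[dup]), collapse = ", "),
      call. = FALSE
    )
  }
  uniq <- words[!dup]
  raw_token_count <- as.integer(raw_token_count)
  stopifnot(raw_token_count >= length(uniq))
  structure(
    list(
      words = uniq,
      source_label = as.character(source_label)[1],
      raw_token_count = raw_token_count
    ),
    class = "neg_lexicon"
  )
}

#' @export
print.neg_lexicon <- function(x, ...) {
  cat(
    "<neg_lexicon> ", length(x$words), " words (", x$raw_token_count,
    " raw tokens) — ", x$source_label, "\n",
    sep = ""
  )
  preview <- utils::head(x$words, 8L)
  cat("  ", paste(preview, collapse = ", "),
      if (length(x$words) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Load the packaged default negative-word lexicon
#'
#' The default list contains 110 printed entries (108 unique words; two
#' entries appear twice in the source list and are collapsed). It was
#' curated from words that carry a strong, context-independent negative
#' connotation and that actually occur in COVID-era tweet streams.
#'
#' @return A [neg_lexicon()] with `source_label = "default negative lexicon"`
#'   and `raw_token_count` equal to the printed list length (110).
#' @export
#' @examples
#' lex <- default_lexicon()
#' "bad" %in% lex$words
default_lexicon <- function() {
  path <- system.file("extdata", "negative_words.txt", package = "negindex")
  lex <- suppressWarnings(read_lexicon(path, source_label = "default negative lexicon"))
  lex
}

#' Read a lexicon from a plain-text file
#'
#' Accepts UTF-8 text with one word per line; commas are also accepted as
#' separators. Lines starting with `#` are comments. Entries are
#' case-folded, trimmed and deduplicated (duplicates raise a warning, not
#' an error). Multi-word entries are rejected: the tokenizer is
#' single-token, so a phrase entry could never match and failing loudly is
#' safer than silently never counting it.
#'
#' @param path path to the lexicon file.
#' @param source_label provenance string; defaults to the file name.
#' @return A [neg_lexicon()].
#' @export
read_lexicon <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) {
    stop("lexicon file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  tokens <- unlist(strsplit(lines, ",", fixed = TRUE), use.names = FALSE)
  tokens <- trimws(tokens)
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) {
    stop("empty lexicon: no valid words in ", path, call. = FALSE)
  }
  neg_lexicon(tokens, source_label = source_label, raw_token_count = length(tokens))
}

#' Write a lexicon to a plain-text file
#'
#' One word per line, UTF-8. Reading the file back with [read_lexicon()]
#' reproduces the same word set.
#'
#' @param lexicon a [neg_lexicon()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "neg_lexicon"))
  writeLines(lexicon$words, path, useBytes = TRUE)
  invisible(path)
}
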