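#' Tokenize tweet text
#'
#' Reduces raw tweet text to the lowercase word tokens against which the
#' negative lexicon is matched. Rules, applied in order:
#' \enumerate{
#'   \item case-fold to lower case;
#'   \item drop URLs entirely (whitespace-delimited tokens starting with
#'     `http://`, `https://` or `www.`);
#'   \item drop user mentions entirely (whitespace-delimited tokens
#'     starting with `@`);
#'   \item split on any character that is not a letter, digit or
#'     apostrophe — this also strips the `#` from hashtags while keeping
#'     the word;
#'   \item strip leading/trailing apostrophes and drop empty tokens.
#' }
#' Apostrophes are kept word-internal, so "don't" stays one token rather
#' than splitting into spurious "don" and "t". Matching downstream is
#' exact-token: "mad" never matches inside "made", and misspellings are
#' not matched.
#'
#' @param text character vector of tweet texts.
#' @return A list of character vectors, one per input text.
#' @export
#' @examples
#' tokenize_text("living in a hotel is not so bad")[[1]]
tokenize_text <- function(text) {
  text <- tolower(as.character(text))
  # URLs and mentions must go before splitting, or their pieces would
  # survive as tokens ("http", "x", "co", "user").
  text <- gsub("(^|\\s)(https?://|www\\.)\\S*", " ", text, perl = TRUE)
  text <- gsub("(^|\\s)@\\S*", " ", text, perl = TRUE)
  toks <- strsplit(text, "[^\\p{L}\\p{N}']+", perl = TRUE)
  lapply(toks, function(tt) {
    tt <- gsub("^'+|'+$", "", tt)
    tt[nzchar(tt)]
  })
}

#' Count negative-word occurrences in a token vector
#'
#' Counts every token that is a lexicon member, with multiplicity: a tweet
#' containing "bad" twice contributes 2. This is occurrence counting, not
#' tweets-containing-any or distinct-words-per-tweet — the daily statistic
#' N(d) sums all occurrences. Counting is deliberately blind to negation
#' and context: "not so bad" scores 1, a documented property of the
#' method.
#'
#' @param tokens character vector of lowercase tokens (one tweet).
#' @param lexicon a [neg_lexicon()].
#' @return List with `negative_count` (integer) and `matched_words`
#'   (character vector of matched tokens, with multiplicity).
#' @export
#' @examples
#' lex <- default_lexicon()
#' count_negative(tokenize_text("living in a hotel is not so bad")[[1]], lex)
count_negative <- function(tokens, lexicon) {
  stopifnot(inherits(lexicon, "neg_lexicon"))
  hit <- tokens %in% lexicon$words
  list(
    negative_count = sum(hit),
    matched_words = tokens[hit]
  )
}

#' Score every tweet in a corpus
#'
#' Tokenizes each tweet and counts lexicon occurrences. The per-tweet
#' scores are what [aggregate_daily()] sums into the daily series.
#'
#' @param corpus corpus tibble (see [read_corpus()]).
#' @param lexicon a [neg_lexicon()].
#' @return A tibble with columns `tweet_id`, `negative_count` and
#'   `matched_words` (list column).
#' @export
score_tweets <- function(corpus, lexicon) {
  stopifnot(inherits(lexicon, "neg_lexicon"))
  toks <- tokenize_text(corpus$text)
  matched <- lapply(toks, function(tt) tt[tt %in% lexicon$words])
  tibble::tibble(
    tweet_id = corpus$id,
    negative_count = vapply(matched, length, integer(1)),
    matched_words = matched
  )
}

#' Export per-tweet scores as JSONL
#'
#' One JSON object per tweet with fields `tweet_id`, `negative_count` and
#' `matched_words`.
#'
#' @param scores tibble from [score_tweets()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  lines <- vapply(seq_len(nrow(scores)), function(i) {
    jsonlite::toJSON(
      list(
        tweet_id = scores$tweet_id[i],
        negative_count = scores$negative_count[i],
        matched_words = scores$matched_words[[i]]
      ),
      auto_unbox = TRUE
    )
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
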