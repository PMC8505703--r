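# Independent oracles, written against the tokenization/counting/OLS rules
# directly rather than sharing code with the package implementation.

# Tokenizer oracle: whitespace-split first, then per-token cleanup with a
# character-level scan (the package implementation instead rewrites the
# whole string with regexes before one split).
oracle_tokenize <- function(text) {
  out <- character(0)
  raw <- strsplit(trimws(text), "\\s+", perl = TRUE)[[1]]
  for (w in raw) {
    if (!nzchar(w)) next
    lw <- tolower(w)
    if (grepl("^(https?://|www\\.)", lw)) next
    if (substr(lw, 1, 1) == "@") next
    chars <- strsplit(lw, "", fixed = TRUE)[[1]]
    word_char <- grepl("^[\\p{L}\\p{N}']$", chars, perl = TRUE)
    chars[!word_char] <- " "
    for (p in strsplit(paste(chars, collapse = ""), " ", fixed = TRUE)[[1]]) {
      while (nzchar(p) && substr(p, 1, 1) == "'") p <- substr(p, 2, nchar(p))
      while (nzchar(p) && substr(p, nchar(p), nchar(p)) == "'") p <- substr(p, 1, nchar(p) - 1)
      if (nzchar(p)) out <- c(out, p)
    }
  }
  out
}

# Brute-force occurrence counter: element-by-element equality loop,
# no set membership operator.
oracle_count <- function(tokens, words) {
  total <- 0L
  for (tok in tokens) {
    for (w in words) {
      if (identical(tok, w)) total <- total + 1L
    }
  }
  total
}

# Matrix-algebra OLS oracle (design matrix + solve of the normal
# equations), for checking the closed-form scalar fit.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  n <- length(y)
  sigma2 <- sum(resid^2) / (n - 2)
  cov_beta <- sigma2 * solve(t(X) %*% X)
  se <- sqrt(cov_beta[2, 2])
  tcrit <- qt(0.975, df = n - 2)
  list(
    intercept = beta[1], slope = beta[2], slope_se = se,
    ci = c(beta[2] - tcrit * se, beta[2] + tcrit * se),
    r_squared = 1 - sum(resid^2) / sum((y - mean(y))^2)
  )
}

# Random messy tweet texts exercising URLs, hashtags, mentions,
# punctuation, apostrophes and repeated words.
random_tweets <- function(n, lexicon, seed = 1) {
  set.seed(seed)
  neutral <- c("hotel", "coffee", "made", "day", "don't", "it's", "the",
               "covid", "news", "today", "O'Brien", "CAFE", "123", "a")
  urls <- c("http://x.co", "https://example.com/a?b=1", "www.site.org/x")
  mentions <- c("@user", "@Someone_1", "@a@b")
  hashtags <- c("#panic", "#StayHome", "#fear2020")
  punct <- c("!!", "...", "?!", ",", " - ", ":)")
  vapply(seq_len(n), function(i) {
    k <- sample(1:12, 1)
    pieces <- sample(
      c(sample(lexicon$words, 4), neutral, urls, mentions, hashtags, punct),
      k, replace = TRUE
    )
    if (runif(1) < 0.3) pieces <- c(pieces, pieces[1]) # force repeats
    paste(pieces, collapse = " ")
  }, character(1))
}

# Small in-memory corpus builder.
make_corpus <- function(texts, days = "2020-03-01", lang = "en") {
  n <- length(texts)
  ts <- if (n == 0L) {
    as.POSIXct(numeric(0), origin = "1970-01-01", tz = "UTC")
  } else {
    as.POSIXct(paste(rep_len(days, n), "12:00:00"), tz = "UTC")
  }
  tibble::tibble(
    id = sprintf("t%04d", seq_len(n)),
    timestamp = ts,
    lang = rep_len(lang, n),
    text = texts
  )
}

write_jsonl <- function(lines, path = tempfile(fileext = ".jsonl")) {
  writeLines(lines, path, useBytes = TRUE)
  path
}
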