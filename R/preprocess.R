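# Document cleaning.
#
# Cleaning mirrors the study's rules: usernames/mentions discarded, hashtags
# converted to plain text, URLs removed, emoji replaced by their name words,
# a small ASCII emoticon list removed, and stop words and contractions kept
# (contraction use separates native from non-native writers, so it is
# signal, not noise). Separately, the explicit disclosure seed phrases
# ("insomnia", "sleepless") are stripped from every document so that no
# classifier can key on the very phrases that defined the labels.

default_emoticons <- function() {
  c(":)", ":(", ":D", ":P", ";)", ":-)", ":-(", "xD", ":/")
}

#' Preprocessing configuration
#'
#' @param seed_phrases lowercase tokens to strip (label-leakage guard).
#' @param strip_mentions,hashtags_to_text,strip_urls,emoji_to_word,
#'   strip_emoticons independent rule flags.
#' @param keep_stopwords,keep_contractions kept for interface completeness;
#'   both default `TRUE` and no rule ever removes stop words or expands
#'   contractions (lemmatization is likewise not applied by default).
#' @param emoji_name_table named character vector mapping emoji characters to
#'   name words.
#' @param emoticons ASCII emoticon tokens to remove.
#' @return object of class `somnia_preprocess_config`.
#' @export
#' @examples
#' clean_tweet("@bob #insomnia sucks http://x.co", preprocess_config())
preprocess_config <- function(seed_phrases = seed_phrase_defaults(),
                              strip_mentions = TRUE,
                              hashtags_to_text = TRUE,
                              strip_urls = TRUE,
                              emoji_to_word = TRUE,
                              strip_emoticons = TRUE,
                              keep_stopwords = TRUE,
                              keep_contractions = TRUE,
                              emoji_name_table = emoji_word_table(),
                              emoticons = default_emoticons()) {
  seed_phrases <- tolower(seed_phrases)
  structure(list(seed_phrases = seed_phrases,
                 strip_mentions = strip_mentions,
                 hashtags_to_text = hashtags_to_text,
                 strip_urls = strip_urls,
                 emoji_to_word = emoji_to_word,
                 strip_emoticons = strip_emoticons,
                 keep_stopwords = keep_stopwords,
                 keep_contractions = keep_contractions,
                 emoji_name_table = emoji_name_table,
                 emoticons = emoticons),
            class = "somnia_preprocess_config")
}

squeeze_ws <- function(x) trimws(gsub("\\s+", " ", x))

mention_pattern <- "(^|\\s)@\\S+"
url_pattern <- "(^|\\s)(https?://|www\\.)\\S+"

emoticon_pattern <- function(emoticons) {
  esc <- gsub("([\\^$.|?*+()\\[\\]{}\\\\])", "\\\\\\1", emoticons, perl = TRUE)
  paste0("(^|\\s)(", paste(esc, collapse = "|"), ")(?=\\s|$)")
}

#' Clean a raw tweet
#'
#' Applies the cleaning rules in a fixed order: hashtag-to-text conversion
#' first (so a hashtagged mention or URL is seen by the later passes), then
#' URL removal, mention removal, emoticon removal, emoji-to-word
#' replacement, whitespace normalisation. Stop words, contractions and case
#' are left untouched (scoring lowercases where needed). The function is
#' vectorised and idempotent:
#' `clean_tweet(clean_tweet(x)) == clean_tweet(x)`.
#'
#' @param x character vector of raw documents.
#' @param config a [preprocess_config()].
#' @return character vector of cleaned documents (possibly empty strings).
#' @export
#' @examples
#' clean_tweet("\U0001F525 night", preprocess_config())  # "fire night"
clean_tweet <- function(x, config = preprocess_config()) {
  stopifnot(inherits(config, "somnia_preprocess_config"))
  if (length(x) == 0) return(character())
  x <- as.character(x)
  if (config$hashtags_to_text) x <- gsub("#+(\\S)", "\\1", x)
  if (config$strip_urls) x <- gsub(url_pattern, " ", x)
  if (config$strip_mentions) x <- gsub(mention_pattern, " ", x)
  if (config$strip_emoticons && length(config$emoticons)) {
    x <- gsub(emoticon_pattern(config$emoticons), " ", x, perl = TRUE)
  }
  if (config$emoji_to_word) {
    for (e in names(config$emoji_name_table)) {
      x <- gsub(e, paste0(" ", config$emoji_name_table[[e]], " "), x,
                fixed = TRUE)
    }
  }
  squeeze_ws(x)
}

#' Strip label-defining seed phrases from cleaned text
#'
#' Removes every token equal (case-insensitively) to one of the seed
#' phrases. Matching is whole-token: "sleeplessness" survives stripping of
#' "sleepless", so derived word forms remain available as genuine linguistic
#' cues while the explicit disclosure phrases are gone. Token order is
#' otherwise preserved; idempotent.
#'
#' @param x character vector of cleaned documents.
#' @param seed_phrases lowercase phrases; defaults to
#'   `c("insomnia", "sleepless")`.
#' @return character vector with seed tokens removed.
#' @export
#' @examples
#' strip_seed_phrases("my insomnia is back")  # "my is back"
strip_seed_phrases <- function(x, seed_phrases = seed_phrase_defaults()) {
  if (length(x) == 0) return(character())
  if (length(seed_phrases) == 0) return(as.character(x))
  pat <- paste0("(^|\\s)(", paste(tolower(seed_phrases), collapse = "|"),
                ")(?=\\s|$)")
  squeeze_ws(gsub(pat, " ", as.character(x), perl = TRUE, ignore.case = TRUE))
}

count_pattern <- function(x, pattern, perl = FALSE, ignore.case = FALSE) {
  m <- gregexpr(pattern, x, perl = perl, ignore.case = ignore.case)
  sum(vapply(m, function(mi) sum(mi > 0), 0L))
}

token_count <- function(x) {
  if (length(x) == 0) return(0L)
  sum(vapply(strsplit(squeeze_ws(x), " ", fixed = TRUE), function(t) {
    sum(nzchar(t))
  }, 0L))
}

#' Preprocess a corpus
#'
#' Cleans every document ([clean_tweet()]), strips seed phrases
#' ([strip_seed_phrases()]), drops documents reduced to empty text, and
#' returns removal statistics satisfying the conservation identity
#' `tokens_in = tokens_out + mentions + urls + emoticons + seed_tokens`
#' (hashtag and emoji conversions preserve token counts). Malformed records
#' (missing or non-character text) are skipped with a warning and counted.
#'
#' @param docs data.frame with columns `user_id` and `raw_text` (plus any
#'   others, carried through), e.g. the `docs` element of a cohort.
#' @param config a [preprocess_config()].
#' @return list with `docs` (cleaned data.frame; column `text` replaces
#'   `raw_text`) and `stats` (named list of counts).
#' @export
preprocess_corpus <- function(docs, config = preprocess_config()) {
  stopifnot(is.data.frame(docs), all(c("user_id", "raw_text") %in% names(docs)))
  raw <- docs$raw_text
  bad <- !vapply(raw, function(x) is.character(x) && !is.na(x) && nzchar(x),
                 TRUE, USE.NAMES = FALSE)
  if (any(bad)) {
    warning(sum(bad), " malformed document record(s) skipped")
    docs <- docs[!bad, , drop = FALSE]
    raw <- raw[!bad]
  }

  tokens_in <- token_count(raw)
  hashtags <- count_pattern(raw, "#\\S")
  # removals are counted after hashtag conversion, mirroring the cleaning
  # order (a hashtagged mention becomes a mention and is then removed)
  base <- if (config$hashtags_to_text) gsub("#+(\\S)", "\\1", raw) else raw
  mentions <- count_pattern(base, mention_pattern)
  urls <- count_pattern(base, url_pattern)
  emoticons <- if (config$strip_emoticons && length(config$emoticons)) {
    count_pattern(base, emoticon_pattern(config$emoticons), perl = TRUE)
  } else 0L
  emoji <- if (config$emoji_to_word) {
    sum(vapply(names(config$emoji_name_table), function(e) {
      count_pattern(raw, e, perl = FALSE)
    }, 0L))
  } else 0L

  cleaned <- clean_tweet(raw, config)
  seed_tokens <- if (length(config$seed_phrases)) {
    count_pattern(cleaned,
                  paste0("(^|\\s)(", paste(config$seed_phrases,
                                           collapse = "|"), ")(?=\\s|$)"),
                  perl = TRUE, ignore.case = TRUE)
  } else 0L
  stripped <- strip_seed_phrases(cleaned, config$seed_phrases)

  empty <- !nzchar(stripped)
  out <- docs
  out$raw_text <- NULL
  out$text <- stripped
  out <- out[!empty, , drop = FALSE]
  rownames(out) <- NULL

  stats <- list(
    docs_in = length(raw) + sum(bad),
    docs_out = nrow(out),
    docs_dropped_empty = sum(empty),
    docs_malformed = sum(bad),
    tokens_in = tokens_in,
    tokens_out = token_count(out$text),
    mentions_removed = mentions,
    urls_removed = urls,
    hashtags_converted = hashtags,
    emoji_converted = emoji,
    emoticons_removed = emoticons,
    seed_tokens_removed = seed_tokens
  )
  list(docs = out, stats = stats)
}
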