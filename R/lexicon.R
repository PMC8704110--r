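# Psycholinguistic category scoring.
#
# An open JSON lexicon maps category names to word lists; a user's score for
# a category is the percent of their tokens matching that category (the
# LIWC convention: scores behave as rates, invariant to text volume). The
# bundled default lexicon is a 14-category stand-in whose names mirror the
# classic psycholinguistic categories and whose word lists are built from
# published exemplars padded with neutral fillers; it is NOT the proprietary
# LIWC2015 dictionary and no numeric agreement with LIWC scores is implied.
# Trailing-asterisk entries ("worr*") match by prefix, as LIWC stems do.

#' Construct and validate a category lexicon
#'
#' @param name identifier for the lexicon.
#' @param categories named list: category name -> character vector of
#'   lowercase words; a trailing `*` marks a prefix stem. Duplicates within
#'   a category are removed.
#' @return object of class `somnia_lexicon`.
#' @export
#' @examples
#' lexicon("tiny", list(negate = c("no", "not", "never")))
lexicon <- function(name, categories) {
  if (!is.list(categories) || length(categories) == 0) {
    stop("lexicon must contain at least one category", call. = FALSE)
  }
  if (is.null(names(categories)) || any(!nzchar(names(categories)))) {
    stop("every lexicon category must be named", call. = FALSE)
  }
  if (anyDuplicated(names(categories))) {
    stop("duplicate category name: ",
         names(categories)[duplicated(names(categories))][1], call. = FALSE)
  }
  categories <- lapply(categories, function(w) unique(tolower(as.character(w))))
  empty <- lengths(categories) == 0
  if (any(empty)) {
    stop("empty word list in category: ", names(categories)[empty][1],
         call. = FALSE)
  }
  structure(list(name = as.character(name), categories = categories),
            class = "somnia_lexicon")
}

#' @export
print.somnia_lexicon <- function(x, ...) {
  cat("<somnia_lexicon '", x$name, "'> ", length(x$categories),
      " categories, ", sum(lengths(x$categories)), " words\n", sep = "")
  invisible(x)
}

#' Load a category lexicon from JSON
#'
#' Expected format: `{"name": "...", "categories": {"cat": ["word", ...]}}`,
#' or a bare top-level object mapping categories to word arrays.
#'
#' @param path path to a JSON file.
#' @return a `somnia_lexicon`.
#' @export
load_lexicon <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("malformed lexicon JSON at '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (is.list(obj) && !is.null(obj$categories)) {
    lexicon(if (!is.null(obj$name)) obj$name else basename(path),
            as.list(obj$categories))
  } else {
    lexicon(basename(path), as.list(obj))
  }
}

#' Write a lexicon to JSON
#' @param lex a `somnia_lexicon`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "somnia_lexicon"))
  jsonlite::write_json(list(name = lex$name, categories = lex$categories),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' The bundled default lexicon
#'
#' Fourteen categories named after the classic psycholinguistic dimensions
#' (first-person "i", negations, swearing, health, drives, present focus,
#' informal markers, cognitive processes, sadness, affiliation, anxiety,
#' death, social, analytic). Word lists start from published exemplars
#' ("worried", "fearful", "nervous"; "crying", "grief", "sad"; "bury",
#' "coffin", "kill"; "damn", "piss"; "no", "not", "never"; "maybe",
#' "perhaps", "guess") padded with neutral same-register fillers. A
#' documented stand-in, not LIWC.
#'
#' @return a `somnia_lexicon`.
#' @export
default_lexicon <- function() {
  lexicon("somnia-default", list(
    i = c("i", "me", "my", "mine", "myself", "im", "i'm", "i've", "i'll",
          "i'd"),
    negate = c("no", "not", "never", "cant", "can't", "dont", "don't",
               "wont", "won't", "neither", "nor", "nothing", "nobody"),
    swear = c("damn", "piss", "fuck", "shit", "hell", "crap", "bitch"),
    health = c("sick", "tired", "pain", "doctor", "medicine", "headache",
               "ill", "flu", "ache", "clinic", "nurse"),
    drives = c("win", "success", "power", "achieve", "goal", "ambition",
               "gain", "lead"),
    focuspresent = c("today", "now", "currently", "moment", "present",
                     "tonight"),
    SemiC = c("lol", "omg", "smh", "idk", "btw", "tbh"),
    cogproc = c("think", "know", "because", "reason", "consider", "realize",
                "understand", "maybe", "perhaps", "guess"),
    sad = c("crying", "grief", "sad", "cry", "tears", "lonely", "miserable",
            "gloomy"),
    affiliation = c("friend", "friends", "family", "team", "together",
                    "community", "buddy", "mate"),
    anx = c("worried", "fearful", "nervous", "tense", "anxious", "afraid",
            "panic", "worry", "worr*"),
    death = c("bury", "coffin", "kill", "dead", "death", "die", "grave",
              "funeral"),
    social = c("talk", "people", "chat", "share", "meet", "party", "visit",
               "call", "text", "hangout"),
    Analytic = c("therefore", "however", "thus", "analyze", "evidence",
                 "conclude", "hence", "furthermore")
  ))
}

# Count tokens matched by a category (exact words + prefix stems).
category_hits <- function(tokens_lower, words) {
  stems <- grepl("\\*$", words)
  hit <- tokens_lower %in% words[!stems]
  if (any(stems)) {
    for (st in sub("\\*$", "", words[stems])) {
      hit <- hit | startsWith(tokens_lower, st)
    }
  }
  sum(hit)
}

#' Score one user's tokens against a lexicon
#'
#' `score(c) = 100 * |tokens in category c| / |tokens|` — percent of tokens,
#' so scores are permutation-invariant and unchanged when every token is
#' duplicated.
#'
#' @param tokens non-empty character vector of tokens.
#' @param lex a `somnia_lexicon`.
#' @return named numeric vector of per-category percentages in \[0, 100\].
#' @export
#' @examples
#' lex <- lexicon("tiny", list(negate = c("no", "not", "never")))
#' score_user(c("no", "not", "happy", "never"), lex)  # negate = 75
score_user <- function(tokens, lex) {
  stopifnot(inherits(lex, "somnia_lexicon"))
  if (length(tokens) == 0) {
    stop("cannot score an empty token list", call. = FALSE)
  }
  tl <- tolower(tokens)
  vapply(lex$categories, function(w) 100 * category_hits(tl, w) / length(tl),
         0)
}

#' Per-user category feature matrix
#'
#' Concatenates each user's cleaned documents into a token stream and scores
#' it against the lexicon. Users with no surviving documents are dropped
#' with a warning.
#'
#' @param pdocs cleaned document data.frame (column `text`), from
#'   [preprocess_corpus()].
#' @param users user table; defines row order and supplies labels.
#' @param lex a `somnia_lexicon`.
#' @return data.frame: `user_id`, `label`, one numeric column per category.
#' @export
lexicon_features <- function(pdocs, users, lex = default_lexicon()) {
  stopifnot(is.data.frame(pdocs), "text" %in% names(pdocs),
            is.data.frame(users), inherits(lex, "somnia_lexicon"))
  toks <- strsplit(tolower(pdocs$text), " ", fixed = TRUE)
  by_user <- split(toks, factor(pdocs$user_id, levels = users$user_id))
  have <- lengths(by_user) > 0
  if (any(!have)) {
    warning(sum(!have), " user(s) with no documents dropped from features")
  }
  scores <- t(vapply(by_user[have], function(tl) {
    score_user(unlist(tl, use.names = FALSE), lex)
  }, numeric(length(lex$categories))))
  keep <- match(names(by_user)[have], users$user_id)
  out <- data.frame(user_id = users$user_id[keep], label = users$label[keep],
                    scores, stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Max-min normalization to \[0, 1\]
#'
#' Linear rescaling by the observed minimum and maximum; order preserving
#' and idempotent. A constant vector has no max-min scale and is an error.
#'
#' @param x numeric vector with at least two distinct values.
#' @return numeric vector in \[0, 1\].
#' @export
#' @examples
#' maxmin_normalize(c(2, 4, 6))  # 0.0 0.5 1.0
maxmin_normalize <- function(x) {
  stopifnot(is.numeric(x))
  if (any(!is.finite(x))) stop("non-finite values", call. = FALSE)
  r <- range(x)
  if (r[1] == r[2]) {
    stop("max-min normalization undefined for a constant vector",
         call. = FALSE)
  }
  (x - r[1]) / (r[2] - r[1])
}

#' Compare category usage between classes
#'
#' Class means of a category score and their absolute and relative
#' difference (relative to the "No" class mean), the quantity behind
#' statements like "insomniacs used anxiety words 10% more".
#'
#' @param features feature data.frame from [lexicon_features()] (or any
#'   data.frame with a `label` column and the category column), or a numeric
#'   vector with `labels` supplied.
#' @param category category column name (ignored for vector input).
#' @param labels optional label vector ("Yes"/"No") for vector input.
#' @return list: `mean_yes`, `mean_no`, `delta`, `relative`.
#' @export
compare_groups <- function(features, category = NULL, labels = NULL) {
  if (is.data.frame(features)) {
    stopifnot(!is.null(category), category %in% names(features),
              "label" %in% names(features))
    x <- features[[category]]
    lab <- features$label
  } else {
    x <- as.numeric(features)
    lab <- labels
  }
  stopifnot(length(x) == length(lab))
  yes <- lab == "Yes"
  if (!any(yes) || all(yes)) {
    stop("both classes must be represented", call. = FALSE)
  }
  mean_yes <- mean(x[yes])
  mean_no <- mean(x[!yes])
  list(mean_yes = mean_yes, mean_no = mean_no,
       delta = mean_yes - mean_no,
       relative = if (mean_no != 0) (mean_yes - mean_no) / mean_no
                  else NA_real_)
}
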