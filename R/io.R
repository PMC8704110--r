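# Plain-text serialisation: the user table as CSV, documents as JSON lines
# (one object per document), lexicons as JSON, feature matrices as CSV.

#' Write a cohort to disk
#'
#' `users.csv` (one row per user) and `docs.jsonl` (one JSON object per
#' document) under `dir`.
#'
#' @param cohort a `somnia_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "somnia_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(cohort$users, file.path(dir, "users.csv"), row.names = FALSE)
  if (!is.null(cohort$docs)) {
    con <- file(file.path(dir, "docs.jsonl"), open = "w", encoding = "UTF-8")
    on.exit(close(con))
    jsonlite::stream_out(cohort$docs, con, verbose = FALSE)
  }
  invisible(dir)
}

#' Read a cohort from disk
#'
#' Reads `users.csv` and, when present, `docs.jsonl` as written by
#' [write_cohort()].
#'
#' @param dir directory path.
#' @return list of class `somnia_cohort` (the `config` element is `NULL`;
#'   the files do not carry the generating configuration).
#' @export
read_cohort <- function(dir) {
  users_path <- file.path(dir, "users.csv")
  if (!file.exists(users_path)) {
    stop("no users.csv under '", dir, "'", call. = FALSE)
  }
  users <- read.csv(users_path, stringsAsFactors = FALSE)
  docs_path <- file.path(dir, "docs.jsonl")
  docs <- NULL
  if (file.exists(docs_path)) {
    con <- file(docs_path, open = "r", encoding = "UTF-8")
    on.exit(close(con))
    docs <- jsonlite::stream_in(con, verbose = FALSE)
  }
  structure(list(users = users, docs = docs, config = NULL),
            class = "somnia_cohort")
}

#' Write a feature matrix to CSV
#' @param features data.frame from [lexicon_features()] or similar.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}
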