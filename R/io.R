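#' Read a trial log from delimited text
#'
#' Reads a comma-separated trial log (header row; booleans written as
#' lowercase `true`/`false`; sides as `left`/`right`; 1-based indices) and
#' validates it with [trial_log()]. Unknown columns are preserved with a
#' warning; a missing required column or inconsistent trial numbering is an
#' error naming the offender.
#'
#' @param path Path to the file.
#' @param strict_sessions Passed to [trial_log()].
#' @return A validated trial-log data.frame.
#' @export
read_trial_log <- function(path, strict_sessions = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", comment.char = "#")
  missing_cols <- setdiff(trial_log_columns, names(df))
  if (length(missing_cols)) {
    stop("trial log ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(df), trial_log_columns)
  if (length(extra)) {
    warning("preserving unknown column(s): ", paste(extra, collapse = ", "))
  }
  for (col in c("session_index", "trial_index")) {
    val <- suppressWarnings(as.integer(df[[col]]))
    if (anyNA(val) && nrow(df)) {
      bad <- which(is.na(val))[1L]
      stop("non-integer `", col, "` at data line ", bad, " of ", path)
    }
    df[[col]] <- val
  }
  for (col in c("correct", "corrective")) {
    val <- parse_bool(df[[col]])
    if (anyNA(val) && nrow(df)) {
      bad <- which(is.na(val))[1L]
      stop("malformed boolean in `", col, "` at data line ", bad, " of ",
           path, " (expected true/false)")
    }
    df[[col]] <- val
  }
  trial_log(df, strict_sessions = strict_sessions)
}

parse_bool <- function(x) {
  out <- rep(NA, length(x))
  out[tolower(x) %in% c("true", "t", "1")] <- TRUE
  out[tolower(x) %in% c("false", "f", "0")] <- FALSE
  out
}

#' Write a trial log as delimited text
#'
#' Writes the comma-separated trial-log format read by [read_trial_log()]:
#' header row, lowercase `true`/`false` booleans, no quoting or row names.
#' Writing and re-reading a log reproduces the records exactly.
#'
#' @param trials A trial-log data.frame.
#' @param path Destination path.
#' @param header Optional character vector written as leading `#` comment
#'   lines (e.g. simulation provenance).
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path, header = NULL) {
  trials <- trial_log(trials)
  out <- trials
  for (col in c("correct", "corrective")) {
    out[[col]] <- ifelse(out[[col]], "true", "false")
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
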