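#' Construct and validate a trial log
#'
#' A trial log is a plain `data.frame` with one row per choice trial and the
#' columns `subject_id`, `species`, `phase` (one of `"training"`, `"task1"`,
#' `"task2"`, `"task1b"`), `task_form` (one of `"food_discrimination"`,
#' `"trays"`, `"gaps"`), `session_index`, `trial_index` (both 1-based),
#' `baited_side`, `chosen_side` (`"left"`/`"right"`), `correct` and
#' `corrective` (logical). `baited_side` encodes the functional (rewarded or
#' accessible) side, so `correct` is true exactly when `chosen_side` equals
#' `baited_side`; `corrective` marks trials inserted by the side-bias
#' correction procedure. `trial_index` runs 1, 2, ... within each
#' (subject, phase) with no gaps.
#'
#' @param df A data.frame with the columns above.
#' @param strict_sessions If `FALSE` (default), `session_index` is re-derived
#'   as `ceiling(k / 10)` over the non-corrective trials of each
#'   (subject, phase); if `TRUE` the stored values are validated instead.
#' @return The validated (and possibly session-reindexed) data.frame.
#' @export
trial_log <- function(df, strict_sessions = FALSE) {
  validate_trial_log(df, strict_sessions = strict_sessions)
}

trial_log_columns <- c("subject_id", "species", "phase", "task_form",
                       "session_index", "trial_index", "baited_side",
                       "chosen_side", "correct", "corrective")

phase_levels <- c("training", "task1", "task2", "task1b")
task_form_levels <- c("food_discrimination", "trays", "gaps")

validate_trial_log <- function(df, strict_sessions = FALSE) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(trial_log_columns, names(df))
  if (length(missing_cols)) {
    stop("trial log is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(df$phase %in% phase_levels)) {
    stop("`phase` must be one of: ", paste(phase_levels, collapse = ", "))
  }
  if (!all(df$task_form %in% task_form_levels)) {
    stop("`task_form` must be one of: ",
         paste(task_form_levels, collapse = ", "))
  }
  for (col in c("baited_side", "chosen_side")) {
    if (!all(df[[col]] %in% c("left", "right"))) {
      stop("`", col, "` must be \"left\" or \"right\"")
    }
  }
  for (col in c("correct", "corrective")) {
    if (!is.logical(df[[col]]) || anyNA(df[[col]])) {
      stop("`", col, "` must be logical with no missing values")
    }
  }
  if (any(df$correct != (df$chosen_side == df$baited_side))) {
    bad <- which(df$correct != (df$chosen_side == df$baited_side))[1L]
    stop("row ", bad, ": `correct` disagrees with chosen vs baited side")
  }
  key <- paste(df$subject_id, df$phase, sep = "\r")
  for (k in unique(key)) {
    rows <- df[key == k, ]
    if (!identical(as.integer(rows$trial_index), seq_len(nrow(rows)))) {
      stop("trial_index is not consecutive from 1 for subject \"",
           rows$subject_id[1L], "\", phase \"", rows$phase[1L], "\"")
    }
    derived <- derive_sessions(rows$corrective)
    if (strict_sessions) {
      if (!identical(as.integer(rows$session_index), derived)) {
        stop("session_index inconsistent with 10-trial blocking for ",
             "subject \"", rows$subject_id[1L], "\", phase \"",
             rows$phase[1L], "\"")
      }
    } else {
      df$session_index[key == k] <- derived
    }
  }
  df$trial_index <- as.integer(df$trial_index)
  df$session_index <- as.integer(df$session_index)
  df
}

# Session index per row: ceiling(non-corrective count / 10); corrective rows
# attach to the session of the most recent non-corrective trial (min 1).
derive_sessions <- function(corrective, trials_per_session = 10L) {
  nc_count <- cumsum(!corrective)
  pmax(1L, as.integer(ceiling(pmax(nc_count, 1L) / trials_per_session)))
}

#' Split one subject-phase trial stream into session blocks
#'
#' Groups the non-corrective trials of a single (subject, phase) stream into
#' consecutive blocks of at most `trials_per_session` trials (the final block
#' may be shorter). Corrective trials remain flagged and are attached to the
#' block within which they occurred, so concatenating the blocks restores
#' the input row order.
#'
#' @param trials A trial log restricted to one subject and phase.
#' @param trials_per_session Block size; default 10 (one daily session).
#' @return A list of data.frames, one per session block, in session order.
#' @export
blockify <- function(trials, trials_per_session = 10L) {
  stopifnot(is.data.frame(trials))
  if (!nrow(trials)) return(list())
  if (length(unique(trials$subject_id)) > 1L ||
      length(unique(trials$phase)) > 1L) {
    off <- trials[which(trials$subject_id != trials$subject_id[1L] |
                          trials$phase != trials$phase[1L])[1L], ]
    stop("blockify() expects one subject and phase; found subject \"",
         off$subject_id, "\", phase \"", off$phase, "\"")
  }
  block <- derive_sessions(trials$corrective, trials_per_session)
  unname(split(trials, block))
}

#' Summarise one subject's performance in one phase
#'
#' Applies a learning criterion to a single (subject, phase) trial stream and
#' reports whether the criterion was reached, the number of errors and trials
#' up to and including the trial of attainment, the totals over the stream,
#' and the number of sessions participated in. Criterion attainment is always
#' evaluated on the non-corrective trials grouped into blocks of
#' `spec$block_size`; `include_corrective` controls whether corrective trials
#' count towards the error and trial tallies (the convention for training
#' phases, where errors from side-bias corrective trials are included) or are
#' dropped (the convention for test phases).
#'
#' @param trials A trial log restricted to one subject and phase, in trial
#'   order.
#' @param spec A [criterion_spec()].
#' @param include_corrective Count corrective trials in the error/trial
#'   tallies? Default `FALSE` (test-phase convention).
#' @return A one-row data.frame (a phase outcome) with columns `subject_id`,
#'   `phase`, `reached_criterion`, `errors_to_criterion`,
#'   `trials_to_criterion`, `total_errors`, `total_trials`,
#'   `sessions_participated`.
#' @export
summarize_phase <- function(trials, spec, include_corrective = FALSE) {
  stopifnot(inherits(spec, "criterion_spec"))
  blocks <- blockify(trials, spec$block_size)  # validates single subject/phase
  nc <- trials[!trials$corrective, , drop = FALSE]
  n <- spec$block_size

  reached <- FALSE
  pos_nc <- NA_integer_  # attainment position within the non-corrective stream
  n_blocks <- ceiling(nrow(nc) / n)
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1L) * n + 1L):min(b * n, nrow(nc))
    det <- detect_criterion(nc$correct[idx], spec)
    if (det$met) {
      reached <- TRUE
      pos_nc <- (b - 1L) * n + det$trial_of_attainment
      break
    }
  }

  counted <- if (include_corrective) trials else nc
  if (reached) {
    if (include_corrective) {
      # row (in the full stream) of the pos_nc-th non-corrective trial
      cut <- which(!trials$corrective)[pos_nc]
    } else {
      cut <- pos_nc
    }
    errors_to <- sum(!counted$correct[seq_len(cut)])
    trials_to <- cut
  } else {
    errors_to <- NA_integer_
    trials_to <- NA_integer_
  }

  data.frame(
    subject_id = if (nrow(trials)) trials$subject_id[1L] else NA_character_,
    phase = if (nrow(trials)) trials$phase[1L] else NA_character_,
    reached_criterion = reached,
    errors_to_criterion = as.integer(errors_to),
    trials_to_criterion = as.integer(trials_to),
    total_errors = sum(!counted$correct),
    total_trials = nrow(counted),
    sessions_participated = max(1L, as.integer(ceiling(nrow(nc) / n))),
    stringsAsFactors = FALSE
  )
}

#' Median and range of a numeric vector
#'
#' The summary reported for small behavioural cohorts: median (mean of the
#' two central values for even n), minimum, maximum and n.
#'
#' @param values Nonempty numeric vector.
#' @return A one-row data.frame with columns `median`, `min`, `max`, `n`.
#' @examples
#' median_range(c(20, 20, 64, 57))  # median 38.5, range 20-64
#' @export
median_range <- function(values) {
  if (!length(values)) stop("`values` must be nonempty")
  if (!is.numeric(values) || anyNA(values)) {
    stop("`values` must be numeric with no missing values")
  }
  data.frame(median = stats::median(values), min = min(values),
             max = max(values), n = length(values))
}
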