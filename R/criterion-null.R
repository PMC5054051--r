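#' Specify a compound learning criterion over a fixed trial block
#'
#' A learning criterion of the kind used in operant two-alternative
#' discrimination experiments: within one block of `block_size` trials the
#' subject must either produce a run of at least `run_length` consecutive
#' correct choices, or make at least `min_correct` correct choices in the
#' full block. At least one of the two clauses must be present. The test
#' criterion used throughout this package's worked examples is 7 consecutive
#' correct, or 9 of 10 correct, in one block of 10 trials; the training
#' criterion is the run clause alone.
#'
#' @param block_size Number of trials per block (session). Default 10.
#' @param run_length Required run of consecutive correct choices, or `NULL`
#'   to disable the run clause. Default 7.
#' @param min_correct Minimum number correct in a completed block, or `NULL`
#'   to disable that clause. Default 9.
#' @param chance_probability Per-trial probability of a correct choice for a
#'   chance-level subject. Default 0.5 (two equiprobable options).
#' @return An object of class `criterion_spec`.
#' @examples
#' criterion_spec()                      # the test criterion: run 7 or 9/10
#' criterion_spec(run_length = 7, min_correct = NULL)  # training criterion
#' @export
criterion_spec <- function(block_size = 10, run_length = 7, min_correct = 9,
                           chance_probability = 0.5) {
  stopifnot(is.numeric(block_size), length(block_size) == 1L, block_size >= 1)
  if (is.null(run_length) && is.null(min_correct)) {
    stop("at least one of `run_length` and `min_correct` must be given")
  }
  if (!is.null(run_length)) {
    stopifnot(is.numeric(run_length), length(run_length) == 1L, run_length >= 1)
    if (run_length > block_size) {
      stop("`run_length` must not exceed `block_size`")
    }
  }
  if (!is.null(min_correct)) {
    stopifnot(is.numeric(min_correct), length(min_correct) == 1L,
              min_correct >= 1)
    if (min_correct > block_size) {
      stop("`min_correct` must not exceed `block_size`")
    }
  }
  stopifnot(is.numeric(chance_probability), length(chance_probability) == 1L,
            chance_probability > 0, chance_probability < 1)
  structure(
    list(block_size = as.integer(block_size),
         run_length = if (!is.null(run_length)) as.integer(run_length),
         min_correct = if (!is.null(min_correct)) as.integer(min_correct),
         chance_probability = chance_probability),
    class = "criterion_spec"
  )
}

#' @export
print.criterion_spec <- function(x, ...) {
  clauses <- c(
    if (!is.null(x$run_length)) {
      sprintf("run of >= %d consecutive correct", x$run_length)
    },
    if (!is.null(x$min_correct)) {
      sprintf(">= %d of %d correct in a completed block", x$min_correct,
              x$block_size)
    }
  )
  cat(sprintf("Learning criterion (block of %d trials, chance q = %g):\n",
              x$block_size, x$chance_probability))
  cat(paste0("  ", paste(clauses, collapse = "  OR  ")), "\n")
  invisible(x)
}

#' Count binary sequences containing a success run
#'
#' Number of binary outcome sequences of length `n` that contain at least one
#' run of `r` or more successes, computed by a dynamic-programming complement
#' recurrence on run-free sequences: with `f(i)` the number of length-`i`
#' sequences containing no run of `r` successes, `f(i) = 2^i` for `i < r` and
#' `f(i) = f(i-1) + f(i-2) + ... + f(i-r)` otherwise (conditioning on the
#' number of leading successes before the first failure). The count returned
#' is `2^n - f(n)`.
#'
#' For the standard 10-trial session and a run criterion of 7, the count is
#' 20 of the 1024 possible sequences.
#'
#' @param n Sequence (block) length.
#' @param r Required run length.
#' @return The count, as a double (exact for `n <= 50`).
#' @seealso [count_run_sequences_bruteforce()] for the exhaustive enumerator
#'   used as an independent oracle in the package's tests.
#' @examples
#' count_run_sequences(10, 7)  # 20
#' @export
count_run_sequences <- function(n, r) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1,
            is.numeric(r), length(r) == 1L, r >= 1)
  n <- as.integer(n); r <- as.integer(r)
  if (r > n) return(0)
  # f[i + 1] = number of length-i sequences with no run of >= r successes
  f <- numeric(n + 1L)
  f[seq_len(min(r, n + 1L))] <- 2^(seq_len(min(r, n + 1L)) - 1L)
  if (n >= r) {
    for (i in r:n) {
      f[i + 1L] <- sum(f[(i - r + 1L):i])
    }
  }
  2^n - f[n + 1L]
}

#' Exhaustively count sequences containing a success run
#'
#' Brute-force enumeration over all `2^n` binary sequences; the independent
#' oracle for [count_run_sequences()]. Guarded to `n <= 20`.
#'
#' @inheritParams count_run_sequences
#' @return The count.
#' @export
count_run_sequences_bruteforce <- function(n, r) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1,
            is.numeric(r), length(r) == 1L, r >= 1)
  if (n > 20) stop("exhaustive enumeration is guarded to n <= 20")
  seqs <- all_outcome_sequences(as.integer(n))
  sum(apply(seqs, 1L, function(s) max_run(s) >= r))
}

# All 2^n outcome sequences as a logical matrix (rows = sequences).
all_outcome_sequences <- function(n) {
  stopifnot(n >= 1, n <= 24)
  m <- matrix(FALSE, nrow = 2^n, ncol = n)
  for (j in seq_len(n)) {
    m[, j] <- bitwAnd(seq_len(2^n) - 1L, bitwShiftL(1L, j - 1L)) > 0L
  }
  m
}

# Longest run of TRUE in a logical vector.
max_run <- function(x) {
  if (!length(x)) return(0L)
  r <- rle(x)
  w <- r$lengths[r$values]
  if (length(w)) max(w) else 0L
}

#' Enumerate the chance-level null of a compound learning criterion
#'
#' Exhaustively enumerates all `2^n` outcome sequences of one trial block and
#' counts those satisfying the compound criterion (run clause OR
#' minimum-correct clause), deduplicated: a sequence meeting both clauses is
#' counted once. Also reports the decomposition into sequences meeting the
#' run clause and sequences meeting only the minimum-correct clause, and the
#' per-session probability that a chance-level subject (per-trial success
#' probability `chance_probability`) meets the criterion. For a fair
#' two-alternative chooser (`q = 0.5`) the probability is the count ratio;
#' for other `q` it is the sum of per-sequence Bernoulli masses while the
#' count fields remain unweighted counts.
#'
#' For the standard test criterion (run of 7, or 9 of 10, in a 10-trial
#' block) the enumeration yields 20 run sequences plus 4 sequences with nine
#' correct but no qualifying run: 24 successful sequences of 1024, a
#' per-session chance probability of about 0.0234 (0.02 at two decimals).
#'
#' @param spec A [criterion_spec()].
#' @return An object of class `session_null`: a list with elements
#'   `n_success_sequences`, `n_total_sequences`, `n_run_sequences`,
#'   `n_min_correct_only`, `p_session`, and `spec`.
#' @examples
#' count_criterion_sequences(criterion_spec())  # 24 of 1024
#' @export
count_criterion_sequences <- function(spec) {
  stopifnot(inherits(spec, "criterion_spec"))
  n <- spec$block_size
  if (n > 24) {
    stop("exhaustive enumeration is guarded to block_size <= 24; ",
         "for a run-only criterion use count_run_sequences()")
  }
  seqs <- all_outcome_sequences(n)
  runs <- apply(seqs, 1L, max_run)
  hits <- rowSums(seqs)
  run_ok <- if (!is.null(spec$run_length)) runs >= spec$run_length
            else rep(FALSE, nrow(seqs))
  min_ok <- if (!is.null(spec$min_correct)) hits >= spec$min_correct
            else rep(FALSE, nrow(seqs))
  success <- run_ok | min_ok
  q <- spec$chance_probability
  p_session <- if (q == 0.5) {
    sum(success) / nrow(seqs)
  } else {
    sum(q^hits[success] * (1 - q)^(n - hits[success]))
  }
  structure(
    list(n_success_sequences = sum(success),
         n_total_sequences = nrow(seqs),
         n_run_sequences = sum(run_ok),
         n_min_correct_only = sum(min_ok & !run_ok),
         p_session = p_session,
         spec = spec),
    class = "session_null"
  )
}

#' @export
print.session_null <- function(x, ...) {
  cat(sprintf("Chance-level null of the learning criterion (block of %d):\n",
              x$spec$block_size))
  cat(sprintf("  %d successful sequences of %d (%d run + %d min-correct only)\n",
              x$n_success_sequences, x$n_total_sequences,
              x$n_run_sequences, x$n_min_correct_only))
  cat(sprintf("  per-session success probability: %.6f\n", x$p_session))
  invisible(x)
}

#' Detect criterion attainment within a (possibly partial) trial block
#'
#' Evaluates a compound learning criterion on the outcomes of one trial
#' block. The run clause can fire on a partial block as soon as the run is
#' complete; the minimum-correct clause is only decidable once the block is
#' complete (length equal to `spec$block_size`). `trial_of_attainment` is the
#' earliest trial at which the criterion is irrevocably satisfied: the last
#' trial of the first qualifying run, or the trial on which the
#' `min_correct`-th success occurs in a completed qualifying block.
#'
#' @param outcomes Logical vector of trial outcomes (`TRUE` = correct), at
#'   most `spec$block_size` long.
#' @param spec A [criterion_spec()].
#' @return A list with `met` (logical) and `trial_of_attainment` (1-based
#'   integer, or `NA_integer_` when unmet).
#' @examples
#' detect_criterion(rep(TRUE, 7), criterion_spec())       # met at trial 7
#' detect_criterion(rep(c(TRUE, FALSE), 5), criterion_spec())  # not met
#' @export
detect_criterion <- function(outcomes, spec) {
  stopifnot(inherits(spec, "criterion_spec"))
  if (anyNA(outcomes) || !is.logical(outcomes)) {
    stop("`outcomes` must be a logical vector with no missing values")
  }
  if (length(outcomes) > spec$block_size) {
    stop("block longer than `spec$block_size`")
  }
  attain <- integer(0)
  if (!is.null(spec$run_length) && length(outcomes) >= spec$run_length) {
    run <- 0L
    for (i in seq_along(outcomes)) {
      run <- if (outcomes[i]) run + 1L else 0L
      if (run >= spec$run_length) { attain <- c(attain, i); break }
    }
  }
  if (!is.null(spec$min_correct) && length(outcomes) == spec$block_size &&
      sum(outcomes) >= spec$min_correct) {
    attain <- c(attain, which(cumsum(outcomes) == spec$min_correct &
                                outcomes)[1L])
  }
  if (length(attain)) {
    list(met = TRUE, trial_of_attainment = min(attain))
  } else {
    list(met = FALSE, trial_of_attainment = NA_integer_)
  }
}

#' Detect a side bias within one session
#'
#' A subject is considered side-biased within a session if it chose the same
#' side on `threshold` or more trials of that session (default 6, evaluated
#' on the non-corrective trials of a 10-trial session).
#'
#' @param sides Character vector of chosen sides (`"left"`/`"right"`) for one
#'   session's non-corrective trials.
#' @param threshold Minimum same-side choices that constitute a bias.
#' @return A list with `biased` (logical) and `preferred_side` (the biased
#'   side, or `NA_character_`).
#' @examples
#' detect_side_bias(c(rep("left", 6), rep("right", 4)))  # biased, left
#' @export
detect_side_bias <- function(sides, threshold = 6) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 1)
  if (!length(sides)) {
    return(list(biased = FALSE, preferred_side = NA_character_))
  }
  if (!all(sides %in% c("left", "right"))) {
    stop("`sides` must be \"left\" or \"right\"")
  }
  n_left <- sum(sides == "left")
  n_right <- length(sides) - n_left
  if (max(n_left, n_right) >= threshold) {
    list(biased = TRUE,
         preferred_side = if (n_left >= n_right) "left" else "right")
  } else {
    list(biased = FALSE, preferred_side = NA_character_)
  }
}
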