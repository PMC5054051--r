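#' Cumulative probability of chance success over repeated sessions
#'
#' Because the learning criterion is assessed afresh in every session, a
#' chance-level subject's probability of having met it at least once grows
#' with the number of sessions. With per-session success probability
#' `p_session`, the cumulative probability over `k_sessions` independent
#' sessions is `1 - (1 - p_session)^k_sessions`.
#'
#' @param p_session Per-session success probability, in (0, 1); see
#'   [count_criterion_sequences()].
#' @param k_sessions Number of sessions, a positive integer.
#' @return The cumulative success probability.
#' @examples
#' cumulative_success_probability(24 / 1024, 10)  # ~0.211
#' @export
cumulative_success_probability <- function(p_session, k_sessions) {
  stopifnot(is.numeric(p_session), p_session > 0, p_session < 1,
            is.numeric(k_sessions))
  if (any(k_sessions < 1)) {
    stop("`k_sessions` must be >= 1 (a tested subject has at least one session)")
  }
  1 - (1 - p_session)^k_sessions
}

#' Combine per-subject probabilities by Fisher's method
#'
#' Combines independent per-subject probabilities into a single test:
#' `chi_sq_total = sum(-2 * log(p_i))` is referred to the upper tail of a
#' chi-square distribution with `2 * length(p)` degrees of freedom (one-tailed).
#' With a single p the combined p equals that p; for 2 degrees of freedom the
#' closed form `p_combined = exp(-chi_sq_total / 2)` holds.
#'
#' @param cumulative_ps Probabilities in (0, 1], one per subject.
#' @param contributions Optional data.frame of per-subject detail, carried
#'   through to the result (as built by [analyze_task()]).
#' @return An object of class `chance_test`: a list with `chi_sq_total`,
#'   `df_total`, `p_combined` and `contributions`.
#' @examples
#' fisher_combined(c(0.05, 0.10, 0.50))
#' @export
fisher_combined <- function(cumulative_ps, contributions = NULL) {
  if (!length(cumulative_ps)) stop("`cumulative_ps` must be nonempty")
  if (!is.numeric(cumulative_ps) || anyNA(cumulative_ps) ||
      any(cumulative_ps <= 0) || any(cumulative_ps > 1)) {
    stop("probabilities must lie in (0, 1]")
  }
  chi <- sum(-2 * log(cumulative_ps))
  df <- 2L * length(cumulative_ps)
  structure(
    list(chi_sq_total = chi,
         df_total = df,
         p_combined = stats::pchisq(chi, df = df, lower.tail = FALSE),
         contributions = contributions),
    class = "chance_test"
  )
}

#' @export
print.chance_test <- function(x, digits = 4, ...) {
  cat("Fisher-combined test of cohort performance against chance\n")
  if (!is.null(x$contributions)) {
    print(format(x$contributions, digits = digits), row.names = FALSE)
  }
  cat(sprintf("  chi-squared = %.*f, DF = %d, combined P = %.4g\n",
              2, x$chi_sq_total, x$df_total, x$p_combined))
  invisible(x)
}

#' Test a cohort's criterion attainment against chance
#'
#' Builds, for each subject's phase outcome, the cumulative probability that
#' a chance-level responder would have met the learning criterion within the
#' sessions that subject was given, and combines the per-subject
#' probabilities by Fisher's method. Subjects that reached the criterion are
#' weighted by the number of sessions they needed
#' (`ceiling(trials_to_criterion / block_size)`); subjects that never reached
#' it still contribute, weighted by the total number of sessions they
#' participated in before testing ceased. Each subject contributes 2 degrees
#' of freedom, so a cohort of 8 subjects gives DF = 16 and a cohort of 6
#' gives DF = 12. Outcomes are expected on the non-corrective trial stream
#' (the test-phase convention of [summarize_phase()]).
#'
#' @param outcomes A data.frame of phase outcomes (rows from
#'   [summarize_phase()], or equivalently columns `subject_id`,
#'   `reached_criterion`, `trials_to_criterion`, `sessions_participated`).
#' @param spec A [criterion_spec()]; sets the per-session null probability
#'   via exact enumeration.
#' @param p_session Override for the per-session success probability, e.g.
#'   a rounded value such as 0.02. Default `NULL` uses the exact enumerated
#'   probability (24/1024 for the standard test criterion).
#' @return A `chance_test` whose `contributions` table has one row per
#'   subject: `subject_id`, `k_sessions`, `p_session`, `p_cumulative`,
#'   `chi_sq_contribution`, `df_contribution`.
#' @export
analyze_task <- function(outcomes, spec = criterion_spec(), p_session = NULL) {
  stopifnot(is.data.frame(outcomes))
  if (!nrow(outcomes)) stop("`outcomes` must contain at least one subject")
  needed <- c("subject_id", "reached_criterion", "trials_to_criterion",
              "sessions_participated")
  missing_cols <- setdiff(needed, names(outcomes))
  if (length(missing_cols)) {
    stop("`outcomes` is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(outcomes$sessions_participated < 1)) {
    stop("every subject must have participated in at least one session")
  }
  if (is.null(p_session)) {
    p_session <- count_criterion_sequences(spec)$p_session
  }
  stopifnot(is.numeric(p_session), p_session > 0, p_session < 1)

  k <- ifelse(outcomes$reached_criterion,
              ceiling(outcomes$trials_to_criterion / spec$block_size),
              outcomes$sessions_participated)
  if (anyNA(k)) {
    stop("reached subjects must have `trials_to_criterion`")
  }
  p_cum <- cumulative_success_probability(p_session, k)
  contributions <- data.frame(
    subject_id = outcomes$subject_id,
    reached_criterion = outcomes$reached_criterion,
    k_sessions = as.integer(k),
    p_session = p_session,
    p_cumulative = p_cum,
    chi_sq_contribution = -2 * log(p_cum),
    df_contribution = 2L,
    stringsAsFactors = FALSE
  )
  fisher_combined(p_cum, contributions = contributions)
}

#' Null calibration of the session-weighted combined test
#'
#' Simulates cohorts of chance-level responders session by session (each
#' session an independent block of `spec$block_size` fair Bernoulli trials,
#' evaluated against the full compound criterion via the exact enumeration of
#' [count_criterion_sequences()]) and returns the combined p-value of
#' [analyze_task()] for each replicate cohort. Subjects stop at their first
#' criterion session or at `max_sessions`; failed subjects are weighted by
#' `max_sessions`, mirroring the stopping rule of the behavioural protocol
#' (a 200-trial cap is 20 ten-trial sessions). Useful for studying the
#' test's actual type-I error, which is larger than the nominal level
#' because failed subjects are assigned the capped cumulative probability
#' rather than a p-value of 1 (see the methods vignette).
#'
#' @param n_subjects Subjects per cohort.
#' @param replicates Number of cohorts to simulate.
#' @param spec A [criterion_spec()].
#' @param max_sessions Session cap per subject (default 20, i.e. 200 trials).
#' @param seed Optional integer seed.
#' @return Numeric vector of `replicates` combined p-values.
#' @export
simulate_null_combined_test <- function(n_subjects = 8, replicates = 1000,
                                        spec = criterion_spec(),
                                        max_sessions = 20, seed = NULL) {
  stopifnot(n_subjects >= 1, replicates >= 1, max_sessions >= 1)
  if (!is.null(seed)) set.seed(seed)
  null <- count_criterion_sequences(spec)
  # membership lookup over all 2^n block patterns
  seqs <- all_outcome_sequences(spec$block_size)
  runs <- apply(seqs, 1L, max_run)
  hits <- rowSums(seqs)
  ok <- (!is.null(spec$run_length) & runs >= (spec$run_length %||% Inf)) |
    (!is.null(spec$min_correct) & hits >= (spec$min_correct %||% Inf))
  n_agents <- n_subjects * replicates
  # session patterns drawn over the 2^n blocks with their Bernoulli masses
  q <- spec$chance_probability
  mass <- q^hits * (1 - q)^(spec$block_size - hits)
  success <- matrix(
    ok[sample.int(length(ok), n_agents * max_sessions, replace = TRUE,
                  prob = mass)],
    nrow = n_agents
  )
  first <- apply(success, 1L, function(s) {
    w <- which(s)
    if (length(w)) w[1L] else NA_integer_
  })
  k <- ifelse(is.na(first), max_sessions, first)
  p_cum <- cumulative_success_probability(null$p_session, k)
  chi <- matrix(-2 * log(p_cum), nrow = replicates, byrow = TRUE)
  stats::pchisq(rowSums(chi), df = 2 * n_subjects, lower.tail = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
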