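#' Define an agent's choice policy
#'
#' Agents emulate the response classes seen in criterion-based
#' two-alternative learning experiments:
#'
#' * `"chance"` — chooses each side with probability 0.5, independently of
#'   history.
#' * `"side_biased"` — chooses `preferred_side` with probability
#'   `bias_strength`, regardless of where the reward is.
#' * `"incremental_learner"` — trial-and-error learner whose per-trial
#'   probability of the correct choice rises with reinforcement:
#'   `a(t) = a0 + (a_inf - a0) * (1 - (1 - learning_rate)^reinforced)`, where
#'   `reinforced` counts rewarded trials experienced in the current task and
#'   `a_inf = 0.98` (never perfect, so responding stays stochastic). Each new
#'   task form starts afresh at `initial_accuracy`.
#' * `"transfer_learner"` — like the incremental learner, but starts the
#'   transfer task at `a0 + transfer_carryover * (a_end_task1 - a0)`;
#'   `transfer_carryover = 1` models spontaneous rule transfer,
#'   0 pure relearning. The retest of the initial task resumes at the
#'   accuracy reached when that task ended.
#'
#' @param policy_kind One of `"chance"`, `"side_biased"`,
#'   `"incremental_learner"`, `"transfer_learner"`.
#' @param subject_id,species Labels carried into the trial log.
#' @param bias_strength Probability of choosing the preferred side, in
#'   \[0.5, 1\] (side-biased agents).
#' @param preferred_side `"left"` or `"right"` (side-biased agents).
#' @param learning_rate Per-reinforcement learning rate in \[0, 1\].
#' @param initial_accuracy Per-trial probability of a correct choice before
#'   any reinforcement, in \[0, 1\].
#' @param transfer_carryover Fraction of learned accuracy retained on a new
#'   task form, in \[0, 1\].
#' @return An object of class `agent_policy`.
#' @export
agent_policy <- function(policy_kind = c("chance", "side_biased",
                                         "incremental_learner",
                                         "transfer_learner"),
                         subject_id = "agent", species = "simulated",
                         bias_strength = 0.9, preferred_side = "left",
                         learning_rate = 0.1, initial_accuracy = 0.5,
                         transfer_carryover = 0) {
  policy_kind <- match.arg(policy_kind)
  stopifnot(bias_strength >= 0.5, bias_strength <= 1,
            preferred_side %in% c("left", "right"),
            learning_rate >= 0, learning_rate <= 1,
            initial_accuracy >= 0, initial_accuracy <= 1,
            transfer_carryover >= 0, transfer_carryover <= 1)
  structure(
    list(policy_kind = policy_kind, subject_id = subject_id,
         species = species, bias_strength = bias_strength,
         preferred_side = preferred_side, learning_rate = learning_rate,
         initial_accuracy = initial_accuracy,
         transfer_carryover = transfer_carryover, asymptote = 0.98),
    class = "agent_policy"
  )
}

#' Define the behavioural protocol
#'
#' The experimental protocol the simulator replays: daily sessions of at
#' most 10 trials; a training criterion of 7 consecutive correct choices
#' within one 10-trial block; a test criterion of 7 consecutive or 9-of-10
#' correct in one block; side bias declared at 6 or more same-side choices
#' in a session and corrected by baiting the non-preferred side until two
#' consecutive correct retrievals; reward side pseudo-randomised with no
#' more than two consecutive same-side placements; a 200-trial cap on the
#' initial learning task, a 100-trial cap on the transfer task, and a single
#' fixed 10-trial retest block. Training has no printed cap in the original
#' protocol; the simulator applies the initial-task cap to training as well
#' so chance-level agents terminate.
#'
#' @param trials_per_session Trials per daily session block.
#' @param training_criterion,test_criterion [criterion_spec()] objects.
#' @param bias_threshold Same-side choices per session that constitute a
#'   side bias.
#' @param bias_correction_exit Consecutive correct corrective trials that
#'   end a correction bout.
#' @param max_same_side Maximum consecutive same-side reward placements in
#'   the pseudo-random order.
#' @param initial_task_cap,transfer_cap,retest_trials,training_cap Phase
#'   trial caps (non-corrective trials).
#' @param max_corrective_bout Safety cap on one correction bout (a fully
#'   deterministic side-biased agent would otherwise never exit).
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(trials_per_session = 10,
                          training_criterion = criterion_spec(
                            block_size = trials_per_session,
                            run_length = 7, min_correct = NULL),
                          test_criterion = criterion_spec(
                            block_size = trials_per_session,
                            run_length = 7, min_correct = 9),
                          bias_threshold = 6, bias_correction_exit = 2,
                          max_same_side = 2, initial_task_cap = 200,
                          transfer_cap = 100, retest_trials = 10,
                          training_cap = 200, max_corrective_bout = 500) {
  stopifnot(trials_per_session >= 1, bias_threshold >= 1,
            bias_correction_exit >= 1, max_same_side >= 1,
            initial_task_cap %% trials_per_session == 0,
            transfer_cap %% trials_per_session == 0,
            retest_trials %% trials_per_session == 0,
            training_cap %% trials_per_session == 0,
            max_corrective_bout >= 1)
  structure(
    list(trials_per_session = as.integer(trials_per_session),
         training_criterion = training_criterion,
         test_criterion = test_criterion,
         bias_threshold = as.integer(bias_threshold),
         bias_correction_exit = as.integer(bias_correction_exit),
         max_same_side = as.integer(max_same_side),
         initial_task_cap = as.integer(initial_task_cap),
         transfer_cap = as.integer(transfer_cap),
         retest_trials = as.integer(retest_trials),
         training_cap = as.integer(training_cap),
         max_corrective_bout = as.integer(max_corrective_bout)),
    class = "protocol_spec"
  )
}

#' Pseudo-randomised reward-side sequence
#'
#' Draws each side uniformly, redrawing any draw that would put the reward
#' on the same side for more than `max_same_side` consecutive trials (with
#' two sides, the redraw is deterministic: the run is simply broken). The
#' generated sequence therefore never contains `max_same_side + 1` equal
#' consecutive sides.
#'
#' @param n Sequence length.
#' @param max_same_side Maximum allowed run of equal sides (default 2).
#' @param seed Optional integer seed.
#' @return Character vector of `"left"`/`"right"`.
#' @export
side_sequence <- function(n, max_same_side = 2, seed = NULL) {
  stopifnot(n >= 1)
  if (max_same_side < 1) stop("`max_same_side` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  state <- new_side_state(max_same_side)
  out <- character(n)
  for (i in seq_len(n)) {
    drawn <- next_side(state)
    out[i] <- drawn$side
    state <- drawn$state
  }
  out
}

new_side_state <- function(max_same_side = 2L) {
  list(last = NA_character_, run = 0L, max_same_side = as.integer(max_same_side))
}

# One pseudo-random side draw; a draw extending the run past max_same_side
# is rejected and redrawn (equivalently, forced to the other side).
next_side <- function(state) {
  side <- sample(c("left", "right"), 1L)
  if (!is.na(state$last) && side == state$last &&
      state$run >= state$max_same_side) {
    side <- setdiff(c("left", "right"), state$last)
  }
  state$run <- if (!is.na(state$last) && side == state$last) state$run + 1L
               else 1L
  state$last <- side
  list(side = side, state = state)
}

other_side <- function(side) if (side == "left") "right" else "left"

# Current per-trial probability of a correct choice for a learning agent.
# The asymptote never drags accuracy below its starting point.
agent_accuracy <- function(agent, a0, reinforced) {
  a_inf <- max(agent$asymptote, a0)
  a0 + (a_inf - a0) * (1 - (1 - agent$learning_rate)^reinforced)
}

# Draw one choice given the baited side; returns chosen side.
agent_choose <- function(agent, baited, a0, reinforced) {
  switch(agent$policy_kind,
    chance = sample(c("left", "right"), 1L),
    side_biased = if (stats::runif(1) < agent$bias_strength) {
      agent$preferred_side
    } else {
      other_side(agent$preferred_side)
    },
    # learners choose the functional side with their current accuracy
    if (stats::runif(1) < agent_accuracy(agent, a0, reinforced)) baited
    else other_side(baited)
  )
}

#' Simulate one agent through one protocol phase
#'
#' Runs an agent trial by trial through one phase of the protocol: the
#' reward side follows the pseudo-random order; the agent chooses by its
#' policy; after each completed session the chosen sides are checked for a
#' side bias and, if one has formed, corrective trials (non-preferred side
#' baited, agent policy still applying) are inserted until
#' `bias_correction_exit` consecutive correct retrievals, after which the
#' pseudo-random order resumes. The phase stops at criterion attainment
#' (immediately for the run clause, at the end of a completed block for the
#' minimum-correct clause), at the phase's trial cap, or after exactly
#' `retest_trials` for the retest phase (which never stops early).
#'
#' @param agent An [agent_policy()].
#' @param phase One of `"training"`, `"task1"`, `"task2"`, `"task1b"`.
#' @param spec A [protocol_spec()].
#' @param task_form Task label recorded in the log (`"food_discrimination"`,
#'   `"trays"` or `"gaps"`).
#' @param start_accuracy Starting per-trial accuracy for learning agents;
#'   default the agent's `initial_accuracy`.
#' @param seed Optional integer seed (omit when driving several phases from
#'   one master-seeded stream).
#' @return A list with `trials` (a trial log), `outcome` (the phase outcome
#'   from [summarize_phase()]; corrective trials are counted in training,
#'   dropped in test phases) and `end_accuracy` (learning agents' accuracy
#'   at phase end).
#' @export
run_phase <- function(agent, phase = c("training", "task1", "task2", "task1b"),
                      spec = protocol_spec(),
                      task_form = "food_discrimination",
                      start_accuracy = NULL, seed = NULL) {
  phase <- match.arg(phase)
  stopifnot(inherits(agent, "agent_policy"), inherits(spec, "protocol_spec"),
            task_form %in% task_form_levels)
  if (!is.null(seed)) set.seed(seed)

  criterion <- if (phase == "training") spec$training_criterion
               else spec$test_criterion
  cap <- switch(phase, training = spec$training_cap,
                task1 = spec$initial_task_cap, task2 = spec$transfer_cap,
                task1b = spec$retest_trials)
  stop_at_criterion <- phase != "task1b"
  a0 <- if (is.null(start_accuracy)) agent$initial_accuracy else start_accuracy
  tps <- spec$trials_per_session

  side_state <- new_side_state(spec$max_same_side)
  reinforced <- 0L
  nc_count <- 0L
  run_len <- 0L
  block_correct <- logical(0)
  block_sides <- character(0)
  baited <- chosen <- character(0)
  correct <- corrective <- logical(0)
  done <- FALSE

  while (!done) {
    drawn <- next_side(side_state)
    side_state <- drawn$state
    b <- drawn$side
    ch <- agent_choose(agent, b, a0, reinforced)
    ok <- ch == b
    if (ok) reinforced <- reinforced + 1L
    nc_count <- nc_count + 1L
    baited <- c(baited, b); chosen <- c(chosen, ch)
    correct <- c(correct, ok); corrective <- c(corrective, FALSE)
    run_len <- if (ok) run_len + 1L else 0L
    block_correct <- c(block_correct, ok)
    block_sides <- c(block_sides, ch)

    if (stop_at_criterion && !is.null(criterion$run_length) &&
        run_len >= criterion$run_length) {
      done <- TRUE
    } else if (nc_count %% tps == 0L) {
      # completed session: minimum-correct clause, cap, then bias check
      if (stop_at_criterion && !is.null(criterion$min_correct) &&
          sum(block_correct) >= criterion$min_correct) {
        done <- TRUE
      } else if (nc_count >= cap) {
        done <- TRUE
      } else {
        bias <- detect_side_bias(block_sides, spec$bias_threshold)
        if (bias$biased) {
          target <- other_side(bias$preferred_side)
          consec <- 0L
          bout <- 0L
          while (consec < spec$bias_correction_exit &&
                 bout < spec$max_corrective_bout) {
            ch <- agent_choose(agent, target, a0, reinforced)
            ok <- ch == target
            if (ok) reinforced <- reinforced + 1L
            consec <- if (ok) consec + 1L else 0L
            bout <- bout + 1L
            baited <- c(baited, target); chosen <- c(chosen, ch)
            correct <- c(correct, ok); corrective <- c(corrective, TRUE)
          }
        }
      }
      run_len <- 0L  # runs never span session blocks
      block_correct <- logical(0)
      block_sides <- character(0)
    }
    if (nc_count >= cap) done <- TRUE
  }

  trials <- data.frame(
    subject_id = agent$subject_id, species = agent$species, phase = phase,
    task_form = task_form,
    session_index = derive_sessions(corrective, tps),
    trial_index = seq_along(baited),
    baited_side = baited, chosen_side = chosen,
    correct = correct, corrective = corrective,
    stringsAsFactors = FALSE
  )
  outcome <- summarize_phase(trials, criterion,
                             include_corrective = phase == "training")
  list(trials = trials, outcome = outcome,
       end_accuracy = agent_accuracy(agent, a0, reinforced))
}

#' Simulate a full counterbalanced cohort experiment
#'
#' Runs each agent through the complete protocol: training on the food
#' discrimination, then the initial learning task (Trays or Gaps,
#' counterbalanced pseudo-randomly within species), then — only if the
#' initial task's criterion was reached within its cap — the transfer task
#' (the other form), and finally — only if both tasks' criteria were
#' reached — a single 10-trial retest of the initial task. One master seed
#' determines the entire cohort log bit-exactly.
#'
#' @param cohort A list of [agent_policy()] objects (ideally at least two
#'   per species, so task order can be counterbalanced; fewer draws a
#'   warning).
#' @param spec A [protocol_spec()].
#' @param seed Master integer seed.
#' @return A list with `trials` (the concatenated trial log), `outcomes`
#'   (one row per subject x phase, from [summarize_phase()]) and
#'   `assignments` (subject, species, first task form).
#' @export
run_experiment <- function(cohort, spec = protocol_spec(), seed = NULL) {
  stopifnot(length(cohort) >= 1,
            all(vapply(cohort, inherits, logical(1), "agent_policy")))
  ids <- vapply(cohort, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids)) stop("subject_id labels must be unique")
  if (!is.null(seed)) set.seed(seed)

  # counterbalance first-task assignment within species
  species <- vapply(cohort, `[[`, character(1), "species")
  first_task <- character(length(cohort))
  for (sp in unique(species)) {
    members <- which(species == sp)
    if (length(members) < 2L) {
      warning("species \"", sp, "\" has fewer than 2 agents; ",
              "task order cannot be counterbalanced within it")
    }
    shuffled <- members[sample.int(length(members))]
    half <- ceiling(length(shuffled) / 2)
    first_task[shuffled] <- rep(c("trays", "gaps"),
                                c(half, length(shuffled) - half))
  }

  logs <- list()
  outcomes <- list()
  for (i in seq_along(cohort)) {
    agent <- cohort[[i]]
    task1_form <- first_task[i]
    task2_form <- other_task(task1_form)

    tr <- run_phase(agent, "training", spec, "food_discrimination")
    logs[[length(logs) + 1L]] <- tr$trials
    outcomes[[length(outcomes) + 1L]] <- tr$outcome
    if (!tr$outcome$reached_criterion) next

    t1 <- run_phase(agent, "task1", spec, task1_form)
    logs[[length(logs) + 1L]] <- t1$trials
    outcomes[[length(outcomes) + 1L]] <- t1$outcome
    if (!t1$outcome$reached_criterion) next

    t2_start <- if (agent$policy_kind == "transfer_learner") {
      agent$initial_accuracy +
        agent$transfer_carryover * (t1$end_accuracy - agent$initial_accuracy)
    } else {
      NULL
    }
    t2 <- run_phase(agent, "task2", spec, task2_form,
                    start_accuracy = t2_start)
    logs[[length(logs) + 1L]] <- t2$trials
    outcomes[[length(outcomes) + 1L]] <- t2$outcome
    if (!t2$outcome$reached_criterion) next

    # retest resumes at the accuracy reached when the initial task ended
    t1b_start <- if (agent$policy_kind %in%
                       c("incremental_learner", "transfer_learner")) {
      t1$end_accuracy
    } else {
      NULL
    }
    t1b <- run_phase(agent, "task1b", spec, task1_form,
                     start_accuracy = t1b_start)
    logs[[length(logs) + 1L]] <- t1b$trials
    outcomes[[length(outcomes) + 1L]] <- t1b$outcome
  }

  list(
    trials = do.call(rbind, logs),
    outcomes = do.call(rbind, outcomes),
    assignments = data.frame(subject_id = ids, species = species,
                             first_task = first_task,
                             stringsAsFactors = FALSE)
  )
}

other_task <- function(form) if (form == "trays") "gaps" else "trays"
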