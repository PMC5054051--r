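test_that("pseudo-random reward sides never repeat beyond the allowed run", {
  s <- side_sequence(1000, seed = 13)
  runs <- rle(s)$lengths
  expect_true(all(runs <= 2))
  expect_true(all(s %in% c("left", "right")))
  # both sides used about equally
  expect_gt(mean(s == "left"), 0.4)
  expect_lt(mean(s == "left"), 0.6)

  expect_length(side_sequence(1, seed = 2), 1L)
  expect_identical(side_sequence(50, seed = 8), side_sequence(50, seed = 8))
  expect_error(side_sequence(10, max_same_side = 0))

  # a looser constraint allows exactly up to its run length
  s3 <- side_sequence(2000, max_same_side = 3, seed = 21)
  expect_true(all(rle(s3)$lengths <= 3))
})

test_that("a perfect learner meets the training criterion at trial 7", {
  agent <- agent_policy("incremental_learner", initial_accuracy = 1)
  res <- run_phase(agent, "training", seed = 4)
  expect_true(res$outcome$reached_criterion)
  expect_equal(res$outcome$errors_to_criterion, 0L)
  expect_equal(res$outcome$trials_to_criterion, 7L)
  expect_equal(nrow(res$trials), 7L)
})

test_that("a hard side bias triggers correction in session one", {
  agent <- agent_policy("side_biased", bias_strength = 1,
                        preferred_side = "right")
  res <- run_phase(agent, "task1", protocol_spec(initial_task_cap = 20),
                   seed = 10)
  first_session <- res$trials[res$trials$session_index == 1L, ]
  expect_equal(sum(first_session$chosen_side[!first_session$corrective] ==
                     "right"), 10L)
  expect_true(any(res$trials$corrective))
  first_corr <- which(res$trials$corrective)[1L]
  expect_equal(first_corr, 11L)  # bout starts right after session 1
  # corrective trials bait the non-preferred side
  expect_true(all(res$trials$baited_side[res$trials$corrective] == "left"))
  # a deterministic bias never exits the bout: the safety cap bounds it
  expect_lte(sum(res$trials$corrective &
                   res$trials$session_index == 1L),
             protocol_spec()$max_corrective_bout)
  expect_false(res$outcome$reached_criterion)
})

test_that("moderately biased agents recover from correction and resume", {
  agent <- agent_policy("side_biased", bias_strength = 0.8)
  res <- run_phase(agent, "task1", seed = 15)
  expect_true(any(res$trials$corrective))
  # corrective trials never advance the non-corrective session count
  nc <- res$trials[!res$trials$corrective, ]
  expect_equal(nc$session_index, rep(seq_len(ceiling(nrow(nc) / 10)),
                                     each = 10)[seq_len(nrow(nc))])
  # outcome tallies exclude corrective trials in test phases
  expect_equal(res$outcome$total_trials, nrow(nc))
})

test_that("chance agents reach the session criterion near the exact rate", {
  set.seed(61)
  agent <- agent_policy("chance")
  spec <- protocol_spec(initial_task_cap = 100)
  sessions <- 0L
  successes <- 0L
  for (i in 1:250) {
    res <- run_phase(agent, "task1", spec)
    k <- res$outcome$sessions_participated
    sessions <- sessions + k
    successes <- successes + res$outcome$reached_criterion
  }
  p_hat <- successes / sessions
  p <- 24 / 1024
  expect_lt(abs(p_hat - p), 4 * sqrt(p * (1 - p) / sessions))
})

test_that("the full experiment gates phases and respects caps", {
  cohort <- c(
    lapply(1:2, function(i) agent_policy("incremental_learner",
                                         subject_id = paste0("L", i),
                                         species = "A",
                                         learning_rate = 0.2)),
    lapply(1:2, function(i) agent_policy("chance",
                                         subject_id = paste0("C", i),
                                         species = "A")),
    lapply(1:2, function(i) agent_policy("side_biased",
                                         subject_id = paste0("B", i),
                                         species = "B",
                                         bias_strength = 0.85)),
    lapply(1:2, function(i) agent_policy("transfer_learner",
                                         subject_id = paste0("T", i),
                                         species = "B",
                                         learning_rate = 0.25,
                                         transfer_carryover = 1))
  )
  spec <- protocol_spec()
  sim <- run_experiment(cohort, spec, seed = 2024)

  # log validates against the trial-log schema
  expect_silent(trial_log(sim$trials, strict_sessions = TRUE))

  for (id in sim$assignments$subject_id) {
    sub <- sim$trials[sim$trials$subject_id == id, ]
    out <- sim$outcomes[sim$outcomes$subject_id == id, ]
    phases <- unique(sub$phase)
    reached <- function(ph) {
      any(out$phase == ph) && out$reached_criterion[out$phase == ph]
    }
    # gating: later phases require earlier criteria
    if ("task1" %in% phases) expect_true(reached("training"))
    if ("task2" %in% phases) expect_true(reached("task1"))
    if ("task1b" %in% phases) expect_true(reached("task1") && reached("task2"))
    # caps on non-corrective trials
    nc <- sub[!sub$corrective, ]
    counts <- table(factor(nc$phase, levels = unique(nc$phase)))
    if ("task1" %in% names(counts)) {
      expect_lte(counts[["task1"]], spec$initial_task_cap)
    }
    if ("task2" %in% names(counts)) {
      expect_lte(counts[["task2"]], spec$transfer_cap)
    }
    if ("task1b" %in% names(counts)) {
      expect_equal(counts[["task1b"]], spec$retest_trials)
    }
  }

  # counterbalancing: both task orders present within each species
  by_species <- split(sim$assignments$first_task, sim$assignments$species)
  for (ft in by_species) expect_setequal(unique(ft), c("trays", "gaps"))

  # a lone-species cohort warns about counterbalancing
  expect_warning(
    run_experiment(list(agent_policy("chance", subject_id = "solo",
                                     species = "Z")),
                   spec, seed = 5),
    "counterbalanced")
})

test_that("one master seed reproduces the cohort log bit-exactly", {
  cohort <- lapply(1:4, function(i) {
    agent_policy(if (i %% 2) "chance" else "incremental_learner",
                 subject_id = paste0("s", i),
                 species = if (i <= 2) "A" else "B", learning_rate = 0.2)
  })
  a <- run_experiment(cohort, protocol_spec(), seed = 314)
  b <- run_experiment(cohort, protocol_spec(), seed = 314)
  expect_identical(a$trials, b$trials)
  expect_identical(a$outcomes, b$outcomes)
  c2 <- run_experiment(cohort, protocol_spec(), seed = 315)
  expect_false(identical(a$trials, c2$trials))
})

test_that("learning rates are recoverable from trials to criterion", {
  spec <- protocol_spec()
  trials_to <- function(lr, reps, seed) {
    set.seed(seed)
    vapply(seq_len(reps), function(i) {
      agent <- agent_policy("incremental_learner", learning_rate = lr)
      out <- run_phase(agent, "task1", spec)$outcome
      if (out$reached_criterion) out$trials_to_criterion
      else out$total_trials
    }, numeric(1))
  }
  slow <- trials_to(0.02, 100, seed = 401)
  fast <- trials_to(0.2, 100, seed = 402)
  expect_gt(stats::median(slow) - stats::median(fast), 20)
})

test_that("transfer carryover separates spontaneous transfer from relearning", {
  spec <- protocol_spec()
  t2_trials <- function(carry, seed) {
    set.seed(seed)
    vapply(1:60, function(i) {
      agent <- agent_policy("transfer_learner", learning_rate = 0.3,
                            transfer_carryover = carry)
      t1 <- run_phase(agent, "task1", spec)
      start <- agent$initial_accuracy +
        carry * (t1$end_accuracy - agent$initial_accuracy)
      t2 <- run_phase(agent, "task2", spec, start_accuracy = start)
      if (t2$outcome$reached_criterion) t2$outcome$trials_to_criterion
      else t2$outcome$total_trials
    }, numeric(1))
  }
  full <- t2_trials(1, seed = 501)
  none <- t2_trials(0, seed = 502)
  # full carryover mostly attains within the first session
  expect_lt(stats::median(full), 11)
  expect_gt(stats::median(none), stats::median(full))
})
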