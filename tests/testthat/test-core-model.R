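test_that("session blocking groups non-corrective trials in tens", {
  t20 <- make_trials(rep(c(TRUE, FALSE), 10))
  blocks <- blockify(t20)
  expect_length(blocks, 2L)
  expect_true(all(vapply(blocks, nrow, integer(1)) == 10L))

  t7 <- make_trials(rep(TRUE, 7))
  expect_length(blockify(t7), 1L)
  expect_equal(nrow(blockify(t7)[[1L]]), 7L)

  expect_length(blockify(make_trials(logical(0))), 0L)
})

test_that("corrective trials attach to their block and order is restored", {
  correct <- rep(TRUE, 25)
  corrective <- rep(FALSE, 25)
  corrective[11:13] <- TRUE  # a corrective bout after the first full session
  tl <- make_trials(correct, corrective)
  blocks <- blockify(tl)
  expect_length(blocks, 3L)
  expect_equal(sum(blocks[[1L]]$corrective), 3L)  # bout rides with block 1
  expect_equal(sum(!blocks[[1L]]$corrective), 10L)
  restored <- do.call(rbind, blocks)
  expect_equal(restored$trial_index, tl$trial_index)
})

test_that("mixed subjects or phases are rejected with the offender named", {
  a <- make_trials(rep(TRUE, 3), subject_id = "a")
  b <- make_trials(rep(TRUE, 3), subject_id = "b")
  expect_error(blockify(rbind(a, b)), "\"b\"")
})

test_that("phase summaries report attainment-based errors and trials", {
  spec <- criterion_spec()
  # an error-free stream attains the run clause at trial 7
  perfect <- summarize_phase(make_trials(rep(TRUE, 10)), spec)
  expect_true(perfect$reached_criterion)
  expect_equal(perfect$errors_to_criterion, 0L)
  expect_equal(perfect$trials_to_criterion, 7L)

  # training stream matching the fastest training row: 0 errors, 7 trials
  gold <- summarize_phase(make_trials(rep(TRUE, 7), phase = "training"),
                          criterion_spec(run_length = 7, min_correct = NULL),
                          include_corrective = TRUE)
  expect_true(gold$reached_criterion)
  expect_equal(gold$errors_to_criterion, 0L)
  expect_equal(gold$trials_to_criterion, 7L)

  # a pure alternator never meets either clause in 200 trials
  alt <- summarize_phase(make_trials(rep(c(TRUE, FALSE), 100)), spec)
  expect_false(alt$reached_criterion)
  expect_true(is.na(alt$trials_to_criterion))
  expect_equal(alt$total_trials, 200L)
  expect_equal(alt$sessions_participated, 20L)
})

test_that("corrective trials count in training tallies but not in test tallies", {
  correct <- c(rep(TRUE, 5), FALSE, rep(TRUE, 4),   # session 1, no criterion
               FALSE, FALSE,                         # two corrective errors
               rep(TRUE, 7))                         # session 2: run of 7
  corrective <- rep(FALSE, 19)
  corrective[11:12] <- TRUE
  tl <- make_trials(correct, corrective, phase = "training")
  spec <- criterion_spec(run_length = 7, min_correct = NULL)

  train <- summarize_phase(tl, spec, include_corrective = TRUE)
  test <- summarize_phase(tl, spec, include_corrective = FALSE)
  expect_equal(test$trials_to_criterion, 17L)   # non-corrective position
  expect_equal(test$errors_to_criterion, 1L)
  expect_equal(train$trials_to_criterion, 19L)  # corrective trials included
  expect_equal(train$errors_to_criterion, 3L)
})

test_that("phase summaries are prefix-monotone after attainment", {
  spec <- criterion_spec()
  set.seed(11)
  for (i in 1:25) {
    stream <- stats::runif(40) < 0.75
    base <- summarize_phase(make_trials(stream), spec)
    if (!base$reached_criterion) next
    longer <- summarize_phase(make_trials(c(stream, stats::runif(20) < 0.5)),
                              spec)
    expect_equal(longer$errors_to_criterion, base$errors_to_criterion)
    expect_equal(longer$trials_to_criterion, base$trials_to_criterion)
  }
})

test_that("median and range follow the mean-of-middle-values rule", {
  expect_equal(median_range(c(20, 20, 64, 57)),
               data.frame(median = 38.5, min = 20, max = 64, n = 4L))
  expect_equal(median_range(5)$median, 5)
  expect_equal(median_range(c(24, 10)),
               data.frame(median = 17, min = 10, max = 24, n = 2L))
  expect_error(median_range(numeric(0)))

  # brute-force agreement on random inputs via explicit sorting
  set.seed(3)
  for (n in sample(1:100, 20)) {
    x <- stats::rnorm(n)
    s <- sort(x)
    med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    got <- median_range(x)
    expect_equal(got$median, med)
    expect_equal(got$min, s[1])
    expect_equal(got$max, s[n])
  }
})

test_that("trial logs are validated field by field", {
  tl <- make_trials(rep(TRUE, 5))
  bad <- tl
  bad$correct[2] <- FALSE  # disagrees with chosen vs baited side
  expect_error(trial_log(bad), "disagrees")
  gap <- tl
  gap$trial_index[4] <- 9L
  expect_error(trial_log(gap), "consecutive")
  side <- tl
  side$chosen_side[1] <- "middle"
  expect_error(trial_log(side), "chosen_side")
  # strict session validation catches a wrong stored index
  wrong <- make_trials(rep(TRUE, 12))
  wrong$session_index <- 1L
  expect_error(trial_log(wrong, strict_sessions = TRUE), "session_index")
})
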