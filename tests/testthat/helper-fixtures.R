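# Build a one-subject trial log from outcome / corrective flags.
# Baited sides alternate (never three in a row); chosen side is derived so
# that `correct` matches the requested outcomes.
make_trials <- function(correct, corrective = rep(FALSE, length(correct)),
                        subject_id = "s1", phase = "task1",
                        task_form = "trays", species = "simulated") {
  n <- length(correct)
  baited <- rep(c("left", "left", "right", "right"), length.out = n)
  chosen <- ifelse(correct, baited,
                   ifelse(baited == "left", "right", "left"))
  trial_log(data.frame(
    subject_id = rep(subject_id, n), species = rep(species, n),
    phase = rep(phase, n), task_form = rep(task_form, n),
    session_index = rep(1L, n), trial_index = seq_len(n),
    baited_side = baited, chosen_side = chosen,
    correct = correct, corrective = corrective,
    stringsAsFactors = FALSE
  ))
}

# Independent brute-force count of length-n binary sequences holding a
# success run of >= r, via exhaustive expansion and run-length encoding.
brute_run_count <- function(n, r) {
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  runs <- apply(grid, 1L, function(s) {
    enc <- rle(as.logical(s))
    w <- enc$lengths[enc$values]
    if (length(w)) max(w) else 0L
  })
  sum(runs >= r)
}

# Classical exact two-tailed Mann-Whitney p for tie-free data, from the
# closed-form null distribution (distribution function, not enumeration).
pwilcox_two_tailed <- function(u_min, n1, n2) {
  if (2 * u_min >= n1 * n2) return(1)
  min(1, 2 * stats::pwilcox(u_min, n1, n2))
}
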