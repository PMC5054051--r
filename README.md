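# trapgaps

Exact statistics and protocol simulation for criterion-based
two-alternative learning experiments — the design used in comparative
cognition studies such as the Trap-Gaps means-end task for parrots, where a
subject repeatedly chooses between a left and a right option (only one
retrievable), tested in daily 10-trial sessions until it meets a learning
criterion of **7 consecutive correct choices, or 9 of 10 correct, within
one session block**, or runs out of trials.

The package is for researchers analysing (or planning) such experiments
with very small cohorts, where everything must be exact:

* **Criterion null by enumeration** — the chance probability of passing the
  criterion within one session, counted over all 2^n outcome sequences of a
  block: 20 sequences hold a run of ≥ 7 correct, 4 more reach 9-of-10
  without such a run, so a chance subject passes a session with probability
  24/1024 ≈ 0.0234 (`count_criterion_sequences()`, with a
  dynamic-programming run counter and brute-force oracle alongside).
* **Session-weighted chance inference** — a subject given *k* sessions has
  cumulative chance-success probability 1 − (1 − p)^k; per-subject
  probabilities (failed subjects included, weighted by the sessions they
  participated in) combine across the cohort by Fisher's method,
  χ² = Σ −2 ln P, DF = 2 per subject (`analyze_task()`).
* **Exact Mann–Whitney U tests** — mid-rank U statistics with exact
  permutation p-values built from the observed multiset, for group
  comparisons at n = 4 vs 4 (`mwu_exact()`, `compare_groups()`).
* **An agent-based protocol simulator** — chance, side-biased, incremental
  and transfer-learning agents run through the complete behavioural
  protocol (training, pseudo-random reward sides with no triple repeats,
  side-bias detection and corrective trials, counterbalanced task order,
  200/100-trial caps, 10-trial retest), emitting trial logs the analysis
  functions consume (`run_experiment()`).
* **Data plumbing** — a plain CSV trial-log format with strict validation
  (`read_trial_log()`/`write_trial_log()`), and the packaged per-subject
  summary table of the eight-parrot Trap-Gaps cohort (`load_table1()`).

## Worked example

```r
library(trapgaps)

count_criterion_sequences(criterion_spec())
#> Chance-level null of the learning criterion (block of 10):
#>   24 successful sequences of 1024 (20 run + 4 min-correct only)
#>   per-session success probability: 0.023438

tab <- load_table1()
compare_groups(tab$training_errors, tab$species)
#>   group median min max n
#>  caique    5.0   0  17 4
#>   macaw    9.5   4  23 4
#> Mann-Whitney U = 5 (U1 = 5, U2 = 11), n1 = 4, n2 = 4
#> exact two-tailed P = 0.4571

analyze_task(table1_phase_outcomes(tab, "task2"))
#> Fisher-combined test of cohort performance against chance
#>  subject_id reached_criterion k_sessions p_session p_cumulative
#>       No. 2             FALSE         10   0.02344      0.21114
#>       No. 4              TRUE          7   0.02344      0.15297
#>       Green             FALSE         10   0.02344      0.21114
#>         Red              TRUE          1   0.02344      0.02344
#>       No. 5              TRUE          4   0.02344      0.09051
#>        Gold               TRUE         5   0.02344      0.11182
#>  chi_sq_contribution df_contribution
#>                3.110               2
#>                3.755               2
#>                3.110               2
#>                7.507               2
#>                4.805               2
#>                4.382               2
#>   chi-squared = 26.67, DF = 12, combined P = 0.00862
```

Reading the output: during training the two species did not differ in
errors to criterion (medians 5 vs 9.5, exact two-tailed P = 0.46 at these
sample sizes). On the transfer task, each of the six presented subjects
contributes the probability that a chance responder would have passed
within the sessions it was given (e.g. subject Red passed in its first
session, P = 0.0234; the two failures contribute their 10-session
cumulative probability 0.211 rather than being dropped); combining them
gives χ² = 26.67 on 12 degrees of freedom — cohort performance clearly
above chance. `reproduce_results()` recomputes the full headline table
(enumeration counts, four U statistics, cohort medians, degrees of
freedom) and reports pass/fail per check.

A thin command-line wrapper with `enumerate`, `analyze`, `mwu`, `simulate`
and `reproduce` subcommands ships in `inst/cli/trapgaps.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "trapgaps.R", package = "trapgaps"))')" reproduce
```

## Simulating a cohort

```r
cohort <- c(
  lapply(1:4, function(i) agent_policy("incremental_learner",
                                       subject_id = paste0("m", i),
                                       species = "macaw", learning_rate = 0.1)),
  lapply(1:4, function(i) agent_policy("transfer_learner",
                                       subject_id = paste0("c", i),
                                       species = "caique", learning_rate = 0.1,
                                       transfer_carryover = 1))
)
sim <- run_experiment(cohort, protocol_spec(), seed = 1)
analyze_task(sim$outcomes[sim$outcomes$phase == "task1", ])
```

One master seed reproduces the entire cohort log bit-exactly. See the
methods vignette (`vignettes/trap-gaps-methods.Rmd`) for the model, its
assumptions, the calibration caveat of the session-weighted combined test,
and every protocol edge choice.

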