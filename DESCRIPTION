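Package: trapgaps
Title: Exact Criterion-Based Analysis and Simulation of Two-Alternative
    Learning Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing criterion-based two-alternative
    discrimination-learning experiments of the kind used in comparative
    cognition (the Trap-Gaps means-end paradigm): exact enumeration of the
    chance probability of meeting a compound learning criterion (a run of
    consecutive correct choices and/or a minimum number correct within a
    fixed trial block), session-weighted cumulative success probabilities
    combined across subjects by Fisher's method, exact permutation
    Mann-Whitney U tests for small samples with ties, trial-log data
    handling, and an agent-based simulator that replays the full
    behavioural protocol (training, counterbalanced task order, side-bias
    detection and correction, stopping rules, retest) so every analysis
    stage can be exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
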