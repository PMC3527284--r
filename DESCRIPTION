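Package: taskfarm
Title: Task Farming for Biochemical Network Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Splits expensive biochemical-model simulation and analysis tasks
    (stochastic simulation ensembles, parameter scans, repeated optimizations
    and parameter estimations, optimization-based global sensitivity analysis)
    into independent parallel jobs, load-balances them to a target per-job
    runtime, executes them on a local process-pool backend that emulates a
    high-throughput-computing job lifecycle (or writes standard submit
    description files for a real pool), classifies failures from job logs, and
    collates per-job outputs into exactly the artifacts a serial run would
    have produced. Ships a minimal mass-action reaction-network engine
    (deterministic ODE and exact Gillespie simulation), two bounded-box
    optimizers, toy model fixtures, and per-task usage accounting with
    speed-up statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
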