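---
title: "Task farming for biochemical network simulation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task farming for biochemical network simulation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taskfarm)
```

# The problem

Stochastic simulation ensembles, parameter scans, repeated optimizations and
parameter estimations, and optimization-based global sensitivity analyses all
share one structure: a base computation repeated many times with independent
inputs. On a single core, a million-repeat ensemble or a 60-optimization
sensitivity analysis can take weeks; on an opportunistic computing pool each
piece can run concurrently, provided someone splits the task into
self-contained jobs, balances their sizes, watches their lifecycle, and
reassembles the outputs into exactly what a serial run would have produced.
`taskfarm` implements that orchestration layer, together with just enough
simulation machinery — a mass-action reaction-network engine and two
bounded-box optimizers — to exercise every path with real workloads.

# Task types and splitting rules

Seven task types are supported. Their split rules are arithmetic contracts,
tested as identities:

* **Global sensitivity analysis** — for each of the $P$ analysed parameters,
  one maximization and one minimization of the target's sensitivity
  coefficient over the parameter box: exactly $2P$ jobs, ordered
  (parameter 1 max, parameter 1 min, parameter 2 max, ...). A 30-parameter
  analysis therefore produces 60 jobs, a 10-parameter one 20, and this is
  also the parallelism ceiling of the task type: more than $2P$ nodes cannot
  help.
* **Stochastic simulation repeat**, **optimization repeat**, **parameter
  estimation repeat** — the user states the total repeat count $n$; the load
  balancer (below) chooses $r$ repeats per job, giving $\lceil n/r \rceil$
  jobs, all carrying $r$ repeats except a final remainder job. The remainder
  is placed last so job runtimes stay as even as possible.
* **Parallel scan** — the parameter grid (a concrete table, a Cartesian
  range product, or a uniform random sample materialized once under the task
  seed before splitting) is cut into `chunk_count` contiguous, non-overlapping
  index ranges whose sizes differ by at most one, larger chunks first.
* **Optimization with different algorithms** — one job per algorithm
  configuration, in list order.
* **Raw mode** — one repeat per job; the user's argument template is
  instantiated per job (`{job}`, `{out}` tokens) and handed to their
  executable.

Every job carries a self-contained YAML document: the model (as a native
structured-text document), the task fragment it must execute, its seed, and
its output filename. A job can therefore run anywhere — in the local pool
emulation, or on a real pool via the generated submit description files —
with no access to the submitting session.

## Reproducibility across partitions

Two seed streams are deliberately distinct. Each *job* is tagged
`base_seed + job_index`, which makes single-job task types (sensitivity,
algorithm sweep) seed-deterministic. Each *repeat* of a repeats-type task is
simulated with `base_seed + g`, where `g` is the repeat's global index across
the whole task, carried into the job document as a repeat offset. The second
stream is what makes collation invisible to chunking: the same 1000 repeats
are simulated whether they are packed as 1×1000, 10×100, or 100×10, so any
partition collates to identical ensembles. The single-repeat benchmark run by
the load balancer draws from a far-offset seed so that measurement never
consumes the task's own stream; the benchmark repeat is discarded, not
counted towards the task.

# Load balancing

The balancer targets a per-job runtime $t$ (default 900 s). It measures the
wall-clock time $s$ of one repeat and packs $\lfloor t/s \rfloor$ repeats per
job, never fewer than one. `floor` rather than `round` keeps the predicted
job time at or under $t$: overlong jobs risk eviction from non-dedicated
machines, which (without checkpointing) forfeits all computation done. When
a single repeat meets or exceeds $t$ — including a benchmark that exceeds its
wall-clock cap and is abandoned — one repeat per job is assigned. A user
override skips measurement entirely and forces one repeat per job, for
workloads known a priori to be long. Wall-clock rather than CPU time is
measured because $t$ trades off against submission and transfer overheads,
which are wall-clock phenomena. The default of 15 minutes balances per-job
submission overhead (dominant when jobs are very short) against under-use of
the pool and eviction risk (when jobs are long); it is site configuration,
and administrators of small or slow pools should revisit it.

Because the package executes in a single R process, the benchmark deadline
is cooperative: the repeat runs to completion and is declared timed out if
it exceeded the cap, rather than being killed mid-flight. The returned value
is the cap in either case, so packing decisions are identical to those of a
pre-emptive implementation; only the benchmarking phase itself can overshoot.

# The execution backend

The local pool backend emulates the lifecycle of a batch scheduler in
process: jobs move `created → idle → running → {completed, evicted, failed}`,
with at most `max_parallel` in the running state at any poll. An evicted job
is requeued (`evicted → idle`) and restarts from scratch — checkpointing is
not modelled, so every attempt's CPU time is charged but only the last
attempt's output survives. A job whose document fails validation is marked
`held` and never executes; this is the backend's model of a malformed
submission. Eviction is injected probabilistically per attempt
(`eviction_rate`, optionally a per-attempt vector such as `c(1, 0)`), since
real eviction is environmental and a test harness needs it on demand. Every
lifecycle event is appended to a per-job log (numbered records:
submit/execute/evict/terminate/held) and to the task's activity log.

For real pools, `write_submit_descriptions()` emits one standard
`key = value` submit description per job — executable, arguments,
`transfer_input_files`, requirements, output/error/log, and a final `queue`
line — that round-trips losslessly through the bundled parser. Actual
submission to a scheduler is out of scope; the files are the deployment
path.

# Failure diagnosis

A failed task is classified from logs alone. A job that was held and shows
no execute record failed *pre-execution*: its specification never became a
running process, which points at the submission machinery. A job that
executed and terminated with a non-zero exit status failed *post-execution*:
the submission was fine and the task itself was set up wrongly. The
probable-cause text is drawn from an editable rule table
(`inst/extdata/failure_rules.tsv`) keyed on phase and log pattern, with
catch-all rows so every failure is classifiable; the shipped mapping is
original to this package. All task files — documents, submit descriptions,
logs, partial outputs — can be packed into a gzipped tar archive with a
deterministic sorted member list for offline inspection. Completion and
failure notifications go to a pluggable sink (callback, file, or log-only;
mail transport is deliberately not built in), exactly once per terminal
event.

# Collation

**Ensembles.** Stochastic-repeat jobs do not return raw trajectories; each
returns, per time point and species, the partial moments $(n, \sum x,
\sum x^2)$. Pooling partial moments is an exact merge — amounts are particle
counts, i.e. integers, so the sums are exact in double precision — and keeps
the per-job transfer bounded regardless of repeat count. The pooled mean is
$\sum x / n$ and the standard deviation uses the sample divisor $n-1$ by
default (the population divisor is a configuration choice; with $n = 1$ the
SD is reported as 0). The output grid of the stochastic engine is the
piecewise-constant left interpolation of the jump process, which is what
makes grids align across repeats and jobs in the first place.

**Scans.** Chunk outputs are concatenated in job order under a single
header; because chunks partition the grid contiguously, the result is
byte-identical to a serial run's file for deterministic subtasks.

**Best-of tasks.** Optimization and estimation repeats report one row per
repeat; the extremal row wins, ties broken by lowest index, and the winning
parameter set is exported as a runnable model document with the values
substituted. Algorithm sweeps additionally report every algorithm whose best
value lies within a configurable tolerance of the extremum (default 0:
exact ties only). Sensitivity tasks tabulate, per parameter, the maximal and
minimal sensitivity found and their range as the *importance*; the range is
this package's definition of importance, chosen because a parameter whose
sensitivity can swing widely across the admissible box is the one that
matters for the target.

# The simulation engine and optimizers

The engine supports mass-action kinetics only — sufficient for every
orchestration path while keeping the engine auditable. Deterministic time
courses assemble $\dot{x} = N v(x)$ from the stoichiometry (reaction rate
$k \prod x^{\nu}$ in particle units) and integrate with an adaptive-step
solver (`deSolve::lsoda`) at relative tolerance $10^{-8}$. Steady states are
found by long-time integration with horizon doubling until the derivative
max-norm drops below $10^{-9}$ (capped at 20 doublings), restarting from the
previous endpoint; Newton iteration was deliberately not used, as the toy
fixtures are all stably attracting. The stochastic engine is the exact
direct-method realization of the jump process with combinatorial
propensities ($\binom{n}{\nu}$ per reactant species, so a 2A self-reaction
has propensity $k\,n(n-1)/2$), fully determined by its seed.

Two optimizers ship, because the orchestration patterns need one stochastic
and one deterministic representative, not an algorithm zoo: a global-best
particle swarm with the constriction-standard coefficients (inertia 0.729,
cognitive and social weights 1.494 — the widely used stabilizing choice;
settings beyond swarm size and iteration count are deliberately not
exposed), positions clamped to the box, fully seed-deterministic; and a
deterministic local search started from the box centre with every probe
clamped to the bounds before evaluation. In dimension two and above the
local search is Nelder–Mead (`stats::optim`); in one dimension, where the
simplex degenerates, golden-section search (`stats::optimize`) is used
instead — both deterministic, so the algorithm keeps its contract.
Maximization negates the objective internally. Progress traces record the
best value so far per step and are monotone by construction.

The per-parameter sensitivity objective is the scaled sensitivity
coefficient $(p_i / y)\,\partial y / \partial p_i$, computed by central
finite differences with a relative step of $10^{-4}$ (absolute floor
$10^{-8}$), falling back to the unscaled derivative when the target is
within $10^{-12}$ of zero. For the birth–death fixture at steady state
($A^* = k/d$) the scaled sensitivities are exactly $+1$ for $k$ and $-1$
for $d$, which the test suite uses as an analytic oracle.

# Accounting

Per task, the usage record stores submission and end times, job count, CPU
hours (summing every attempt, excluding queueing) and wall-clock hours
(submission to completion, including queueing), and the speed-up factor
CPU/wall — the task's effective acceleration over a sequential single-core
run. The store is a flat append-only TSV; aggregates (task count, totals,
mean and maximum speed-up) are recomputed from it on demand. In the local
emulation, sleep-based workload stubs consume no measurable processor time,
so stub documents may declare a nominal per-attempt CPU cost that the
backend charges instead; real jobs are charged their measured process CPU
time.

# Fixtures and the synthetic estimation generator

The catalog holds four toy networks — birth–death (stationary law Poisson
with mean and variance $k/d = 10$), reversible isomerization (conserved
total of 50), dimerization (second order), and a three-variable mass-action
relaxation oscillator of Oregonator type standing in for oscillatory
signalling models — plus sleep-based workload stubs of configurable
duration. The estimation-dataset generator simulates a catalog model
deterministically and adds i.i.d. Gaussian noise of stated SD
(default case: the decay model observed at 20 uniform time points over 5
time units, SD 0.01 in particle units), recording the generating parameters
so recovery is checkable against a known truth.

The generator emulates additive homoscedastic observation noise on a
correctly specified model. It does not emulate model misspecification,
heteroscedastic or correlated noise, missing observations, or intrinsic
stochasticity in the fitted dynamics — so passing recovery tests demonstrate
that the orchestration and optimizers work, not that this estimation recipe
is adequate for any real dataset.

# Problem sizes and numerical tolerances used in the checks

The shipped checks run at desk scale on one core: ensembles of 1000 repeats
(chunking invisibility, compared at $10^{-9}$ relative) and 2000 seeds
(stationary mean within three standard errors, variance within 15%),
a 100-point scan in four chunks compared byte-wise against its serial run,
20-repeat estimations (12-particle, 25-iteration swarms) recovering the
generating rate constant within 5%, and splitter/balancer identities that
are exact by construction. Pool-scale measurements — thousand-node
wall-clock times and the speed-up factors achievable there — are inherently
properties of a deployment, not of this code, and are covered instead by
the accounting identities and the lifecycle property tests.

# Known limitations

* Kinetics are mass action only; arbitrary rate laws, events, and
  assignments are out of scope, as is any hybrid ODE/SSA solver.
* The local backend interleaves jobs in one process; `max_parallel` bounds
  the emulated running set, not host CPU usage.
* Submit description files are written and validated but never handed to a
  real scheduler; ClassAd evaluation, priorities, and checkpointing are not
  modelled.
* The benchmark deadline is cooperative (see above).
* Optimizer termination is by iteration/evaluation caps only; no
  convergence-based stopping is offered.
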