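---
title: "Two-phase stochastic surgery scheduling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase stochastic surgery scheduling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orsched)
```

## The problem

A hospital operating theater runs a fixed master surgery schedule (MSS):
each operating room (OR) on each weekday forms an *OR block* of ordinary
length $L$ (480 min by default) assigned to one surgical specialty, with
a hard overtime cap $H$ (60 min).  A waiting list mixes *inpatients*
(longer, more variable procedures; rarely absent; costly to cancel) and
*outpatients* (shorter procedures; no-show rate three times higher;
waiting in the clinic weighs more).  Three sources of uncertainty act on
any plan: the realized operating time (ROT) deviates from the estimate
(EOT), emergency patients arrive during the day and must be operated in
the next available moment, and scheduled patients fail to show up.

`orsched` plans a week in the two phases used in practice:

1. **Advance scheduling** (assignment): choose which patients to take
   from the waiting list and place each into an OR block of their
   specialty.
2. **Allocation scheduling** (sequencing + timing): for each block, fix
   the order of its surgeries and a scheduled start time $t_i$ for each,
   deciding where to place slack.

The two stages optimize five costs: scheduling costs of *unscheduled*
patients (indirect waiting), cancellation costs, direct waiting costs
(minutes between scheduled and actual start), idle-time cost and
overtime cost.

## Random variables

Each scenario draws, independently:

* $\rho_i$ — ROT of patient $i$, lognormal with *arithmetic* mean
  $\mu_i$ and SD $\sigma_i$.  The log-scale parameters are obtained by
  moment matching: $s^2 = \log(1 + (\sigma/\mu)^2)$,
  $m = \log\mu - s^2/2$.
* $\theta_i$ — presence, Bernoulli$(1 - r_i)$ with no-show rate $r_i$
  (0.08 inpatients, 0.24 outpatients).
* $\delta_{jk}$ — emergency surgery duration in block $(j,k)$: with
  probability $p^{em} = 0.2$ a lognormal(93, 60) draw truncated at 240
  min, else 0.  Truncation is implemented by *rejection* (resampling
  draws above the cut) rather than clipping, which would put an atom at
  240 and bias the mean; below the cut the density keeps its lognormal
  shape.
* $\tau_{jk}$ — emergency arrival, uniform on $[0, L]$ when an
  emergency exists, 0 otherwise.  Independent per-block arrivals make
  the theater-wide arrivals a Poisson process with rate
  $p^{em}\,|J|$ per day.

Each patient and block owns a deterministic sub-stream derived from the
master seed and its index, so enlarging a waiting list never perturbs
the draws of existing patients — a prerequisite for reproducible
incremental experiments.

## The synthetic instance generator

No patient-level data ships with the package; instances are generated
from published summary statistics:

* **Procedure groups.** 28 lognormal duration components across five
  specialties (cardiology, gastroenterology, gynecology, orthopedics,
  urology), each with a within-specialty frequency, a mean and an SD in
  minutes.  Components come in two variability classes with design
  coefficients of variation near 0.151 and 0.202; the package labels a
  group LCV when $\sigma/\mu < 0.175$ (the midpoint).  Printed
  frequencies are normalized to sum exactly to one per specialty.
* **MSS.** 9 ORs over 5 weekdays, 26 blocks, with a fixed per-OR
  specialty pattern.  The source table fixes the per-OR specialty
  multiset but not every weekday; the shipped default fills consecutive
  days from Monday (OR 9 opens Tuesday, keeping its Monday empty) and is
  fully overridable through the instance file.
* **Patients.** Specialty ~ the case-mix shares (14.32 / 18.76 / 30.43 /
  15.90 / 20.59 %), group ~ the specialty's frequencies, and the EOT is
  the group mean.  LCV patients are outpatients with probability 0.7,
  HCV patients with probability 0.3.  Scheduling costs are uniform on
  $\{10, 20, \ldots, 100\}$ (grid step $\Delta = 10$); cancellation
  costs are $4\times$ (inpatients) or $2\times$ (outpatients) the
  scheduling cost; per-minute waiting costs are uniform on
  $[1/360, 1/36]$ (inpatients) or $[1/180, 1/18]$ (outpatients), so
  outpatient waiting weighs twice as much on average.

What the generator does *not* emulate: correlation between durations in
the same block (shared team fatigue, equipment failures), time-varying
no-show behaviour, urgency dynamics while waiting, and ward/bed
capacity.  Green tests therefore certify the optimization and
simulation machinery under the stated stochastic model, not performance
on any particular hospital's data.

## Advance stage: chance-constrained assignment

Per specialty $s$, binary $x_{ijk}$ assigns patient $i$ to block
$(j,k)$.  Constraints: each patient at most once; the deterministic EOT
load $\sum_i \mu_i x_{ijk} \le L_{jk}$; and a chance constraint

$$\mathbb P\Big[\delta_{jk} + \sum_i \theta_i \rho_i x_{ijk} > L_{jk} + H\Big] \le \alpha$$

estimated on a Monte Carlo sample: a binary per (block, scenario) marks
an overload, and at most $\lfloor \alpha |S| \rfloor$ scenarios may be
marked per block.  The big-M of each overload row is the tightest valid
constant, $\max(0, \delta + \sum_i \theta\rho - (L+H))$, and scenarios
that cannot overload even with every patient assigned generate no binary
at all — this keeps the LP relaxation strong and the model small.

The objective is hierarchical: the total scheduling cost of unscheduled
patients sits on top; below it, three *patient-mix proxies* weighted by
$\beta = (\beta_1, \beta_2, \beta_3)$: the maximum per-block sum of
cancellation costs, the maximum per-block sum of waiting costs, and the
total absolute deviation of expected block utilizations from their
mean.  Standardization constants $b_2, b_3$ bring the proxies to a
common scale and $b_1 = \Delta / (1 + m_s \max c^{canc})$ scales the
whole bottom level below one scheduling-cost grid step, so proxies can
reorder only solutions that tie on the top level.  The first two
proxies are epigraph variables (exact because minimized); the third
uses the standard $d^+ - d^-$ absolute-value split.  After solving, the
package recomputes all proxies and the per-block overload frequencies
*from the assignment itself*; the solver's word is never taken for the
chance constraint.

## Allocation stage: two-stage stochastic MILP

Within one block, the first stage picks immediate-successor binaries
$o_{ii'}$ and start times $t_i$ (first surgery at 0, planned
completions non-overlapping and within $L$).  The second stage is the
realized timeline under the real-time policies:

* surgeries run in the planned order and never start early;
* a no-show collapses its slot at the scheduled moment, at zero cost;
* a surgery is cancelled exactly when its *expected* completion
  (actual start + EOT) would exceed $L + H$;
* the emergency starts at its arrival if the OR is idle, otherwise at
  the completion of the surgery in progress; emergencies are never
  cancelled and may run past $L + H$ (the overtime cap is a policy on
  electives).

The extensive-form MILP carries one copy of the timeline per scenario.
Two modeling choices matter for correctness:

* **Every recourse variable is pinned.**  Cancellation can be *cheaper*
  than overtime, so nothing may be left to the solver's discretion:
  start times get both max-branches (one selector binary per patient
  and scenario), the cancellation equivalence is enforced in both
  directions (with a $10^{-6}$-min strictness margin on the cancel
  side), and the emergency idle gap is fixed by an idle-vs-busy
  indicator.  With the first stage fixed, the model has exactly one
  objective value — the one the algorithmic simulation computes.  This
  dual-route equivalence is asserted on hundreds of randomized cases in
  the test suite.
* **The insertion point lives on the auxiliary timeline.**  The
  emergency is inserted after the elective whose start interval
  contains $\tau$ *on the emergency-free (auxiliary) timeline*, whose
  prefix coincides with the actual one up to the insertion.  Conditions
  phrased on post-insertion actual starts are vacuous (insertion itself
  pushes the successor past $\tau$) and would let the model insert too
  early.  Degree constraints ($\le 1$ successor and predecessor) are
  added to the printed sequencing constraints; together with the
  time-ordering they force a single chain.

Big-M constants are per-scenario horizon bounds
$L + H + \sum\rho\theta + \delta + \tau$, small enough (a few thousand
minutes) that solver tolerances stay far below the cost scale.
Emergency-free scenarios drop the whole emergency apparatus and share
one timeline copy.

**Solvers.**  The classic SAA solves the extensive form on the full
sample — reliable only for small blocks, which is precisely the regime
the package's defaults expect.  *N-fold SAA* (default $N = 10$) solves
the model on $N$ disjoint folds with budget `time_limit / N` each
(equal split; the total block budget stays at the configured 5
minutes), re-evaluates every fold incumbent on the *entire* sample with
the algorithmic recourse — reported costs are never the optimistic fold
objectives — and keeps the best, ties going to the lowest fold index
for determinism.  MILPs are solved by HiGHS through SciPy's
`milp` interface, reached by a batch JSON bridge that amortizes
interpreter startup over many small models.

## BRKGA

For larger blocks a biased random-key genetic algorithm searches
sequencing and timing jointly.  A chromosome holds $2|I|$ genes in
$[0,1]$: the first half orders the surgeries (ascending gene value,
ties broken by patient id so file-loaded chromosomes stay
deterministic); the second half splits the scheduled idle time
$G = L - \sum_i \mu_i$ proportionally into slacks after each surgery,
the last share ending the block.  An all-zero timing half (measure zero
under random initialization, but the decoder must be total) decodes to
a back-to-back schedule.  Every chromosome decodes to a feasible
schedule, so the whole population contributes to the search.  Evolution
is the standard elitist scheme — elites copied (fraction 1/4), mutants
injected (1/5), the rest bred from an elite and a non-elite parent with
per-gene elite inheritance probability 1/2, population 50 — with
counts floored and the remainder filled by crossover.  Fitness is the
sample-average recourse cost of the decoded schedule, computed by the
vectorized simulation kernel (all scenarios advance through the patient
sequence simultaneously).  Termination is generation- or budget-driven.

## Evaluation, sweep, and reporting

The discrete-event evaluator replays a full weekly schedule under fresh
scenarios.  *Bernoulli* mode keeps the at-most-one-emergency-per-block
assumption and reuses the recourse kernel unchanged; *Poisson* mode
draws a Poisson number of emergencies per block (same mean $p^{em}$)
and inserts them in arrival order, FIFO at the OR — an emergency
arriving while a previous one operates waits for it.  Elective draws
are shared between modes under one seed, so mode comparisons are
paired.  Reported are per-block-average cost components, their sum, the
mean emergency waiting time, and per-class (inpatient/outpatient)
summaries: mean scheduled start, mean direct wait, cancellation
probability among present patients.

`run_sweep()` ranges $\alpha \in \{0.05, 0.10, 0.15\}$ against the
three unit $\beta$ vectors (nine configurations by default), solves
both stages per configuration on one shared scenario sample, and picks
the configuration minimizing

$$Z = \sum_{\text{unscheduled}} c^{sched}_i +
      \sum_{(j,k)} \mathbb E[\text{block cost}],$$

with empty blocks contributing their idle and emergency costs.  The
default block-level policy uses N-fold SAA up to six patients and BRKGA
above — the regime split the solver comparison motivates.  Patient-mix
structure is summarized by the per-block Gini impurity
$GI = 1 - (n_{in}/|I|)^2 - (n_{out}/|I|)^2$ normalized by its upper
bound $1 - f_{in}^2 - f_{out}^2$.

## Numerical choices and degenerate inputs

* Cancellation ties ($\hat q_i + \mu_i = L + H$ exactly): the surgery
  is operated; the MILP enforces strictness with a $10^{-6}$ margin,
  and continuous durations make ties measure-zero.
* Emergency arrival ties with a start time: interval membership is
  closed on the left; again measure-zero.
* Empty blocks, empty waiting lists, single-patient blocks, $r_i = 0$
  and $p^{em} = 0$ all evaluate through the same code paths and are
  covered by tests.
* Solver round-off on decoded start times is snapped onto the feasible
  timing polytope before a schedule object is constructed.

## Problem sizes used by the shipped tests

The test suite keeps models at sizes where open-source MILP optimality
is provable: oracle equivalences use blocks of up to 4 patients per
scenario copy, enumeration cross-checks up to 8 patients and 2 blocks
with 50-scenario samples, the chance-constraint audits run a 40-patient
week on 200 scenarios, and the directional regressions use a
100-patient waiting list against a two-day (17-block) MSS cut so that
capacity binds and the assignment trade-off is visible.  Monotonicity
of the advance optimum in $\alpha$ is asserted through proven solver
bounds (the dual bound at the looser level may not exceed the incumbent
at the tighter one), which keeps the check rigorous when a budget stops
the solver short of a certificate.  Production-scale runs (waiting
lists of 500–1100, samples of 1000) use the same code paths with larger
budgets.

## Known limitations

* The two-phase decomposition is heuristic; jointly optimal
  assignment + sequencing is out of reach at realistic sizes and out of
  scope here.
* The chance constraint is sample-based; guarantees hold on the
  training sample, and fresh-sample overload rates fluctuate around
  $\alpha$ with binomial noise.
* The classic SAA degrades beyond roughly six patients per block by
  design of the experiment; the package returns an honest
  `infeasible_within_limit` status rather than stretching budgets.
* Emergency routing across ORs, dedicated emergency rooms, week-over-
  week rolling horizons and downstream bed resources are not modeled.
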