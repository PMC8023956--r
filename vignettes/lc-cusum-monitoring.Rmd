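---
title: "LC-CUSUM competency monitoring: model, operating characteristics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LC-CUSUM competency monitoring: model, operating characteristics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lccusum)
```

## The sequential test

Classical CUSUM charts monitor an in-control process and raise an alarm
when quality *deteriorates*. Competency monitoring inverts this: the null
hypothesis is that the learner is **not yet adequate**, and the chart
signals when the accumulated evidence rejects it. Let `p1` be the failure
probability of an adequate performer and `p0 = p1 + delta` that of an
inadequate one. After each procedure the score moves by the Bernoulli
log-likelihood ratio of "adequate" against "inadequate", is clamped at a
holding barrier, and competency is declared when it reaches the limit `h`:

$$S_t = \max(0,\; S_{t-1} + W_t), \qquad
W_t = \begin{cases}
\log\frac{1-p_1}{1-p_0} & \text{procedure passed}\\[2pt]
\log\frac{p_1}{p_0} & \text{procedure failed,}
\end{cases}
\qquad \text{signal when } S_t \ge h.$$

```{r increments}
design <- lc_design(acceptable_failure_rate = 0.10, equivalence_delta = 0.05,
                    signal_limit = 0.74, horizon = 50)
c(success = design$success_increment, failure = design$failure_increment)
```

The defaults are the deployed monitoring design: `p1 = 0.10` (an adequate
learner fails 10% of procedures), `delta = 0.05`, `h = 0.74`, and at most
50 procedures monitored. The increments are kept at full floating
precision; the familiar `+0.057` / `-0.405` are their 3-decimal
presentation. Thirteen consecutive successes, and no fewer, reach the
limit, because `12 × 0.05716 = 0.686 < 0.74 ≤ 13 × 0.05716 = 0.743`.

Two numerical conventions matter and are fixed package-wide:

* **Signal comparison is `>=`.** This makes the continuous chart
  (`13 × 0.05716 ≥ 0.74`) and the integer variant below (13 steps of +1
  against a limit of 13) signal at the same consecutive-success count.
* **The holding barrier is applied after every update.** The continuous
  chart clamps at 0; each integer level clamps at its own floor.

## The integer-scored program

For teaching, the same test is easier to read in whole points: +1 per
success, −7 per failure, limit 13. The curriculum stacks three competency
levels — repeated K-wire placement in one patient (CL0), K-wire placement
across varying patients (CL1), and the full DHS procedure (CL2) — and the
program score is bound to 0–13, 13–26 and 26–39 across them, so the fastest
possible pass takes `3 × 13 = 39` flawless procedures. Each level allows at
most 50 procedures.

```{r program}
prog <- run_integer_program(rep(list(rep(TRUE, 13)), 3), lc_program_design())
prog
```

A failure inside a level clamps at that level's floor (a failure from 14
points at CL1 lands on 13, not 7): cleared levels are never re-opened, and
early failures are punished less than late ones because of the barrier.
Sequences longer than a cap are truncated with a warning rather than
rejected; `allow_overrun = TRUE` keeps consuming a failed level's outcomes
and still evaluates later levels, recording the extended trace while the
program verdict remains failed — mirroring programs that let a determined
learner keep training past the formal cap.

## Operating characteristics: exact DP and Monte Carlo

The design question — "what is the probability an adequate learner is
declared competent within N procedures, and how long does it take?" — is
answered exactly. Because the two increments are incommensurable, a rounded
score grid would accumulate discretisation error; instead the forward
dynamic program tracks probability mass on the *exact* set of reachable
clamped scores (every reachable score is a clamped lattice combination
`i·W_s + j·W_f`; scores are merged only when equal to within 1e-9, and for
the deployed design only a few dozen states are ever live). Mass at or
above `h` is absorbed into the run-length distribution.

```{r oc}
signal_probability_exact(design, 0.10)
```

The Monte Carlo estimator (`signal_probability_mc`) exists as an
independent stochastic check of the DP, not as the primary method; every
stochastic function in the package takes a mandatory seed, and the test
suite holds the two within Monte-Carlo error across a grid of failure
rates. For the integer program, levels are probabilistically identical
after floor-shifting, so with independent procedures at a constant failure
rate the program pass probability is the single-level probability cubed
(`program_pass_probability`), which the suite verifies against direct
cohort simulation.

`calibrate_limit` searches a grid of candidate limits (default step 0.01,
the precision at which `h` is quoted) because the signal probability is a
step function of `h`; it returns the largest grid value still meeting the
requested power and reports the achieved probabilities at both the
acceptable and unacceptable rates.

### The published 91% / 12% pair

The deployed design is quoted as giving a 91% probability of declaring
competency for an adequate performer and 12% for an inadequate one over 50
procedures, but the computation behind those figures is not on record. The
package computes the candidates exactly; readers can judge the
correspondence themselves:

```{r readings}
# single-chart reading: one continuous chart, h = 0.74, 50 procedures
c(at_p1 = signal_probability_exact(design, 0.10)$signal_probability,
  at_p0 = signal_probability_exact(design, 0.15)$signal_probability,
  at_030 = signal_probability_exact(design, 0.30)$signal_probability)

# program-level reading: all three integer levels within 50 procedures each
c(at_p1 = program_pass_probability(lc_program_design(), 0.10),
  at_p0 = program_pass_probability(lc_program_design(), 0.15))
```

The single-chart probability at the acceptable rate matches the quoted
true-positive figure (0.90 vs 91%). Neither reading reproduces 12% at the
stated unacceptable rate 0.15 (0.68 single-chart, 0.35 program-level); the
single-chart probability at a much higher failure rate of 0.30 does equal
0.118. The quoted pair is therefore treated as a design description, not a
verification target: the suite instead asserts properties the exact
computation must satisfy (agreement with Monte Carlo within sampling error,
monotonicity in rate, horizon and limit, and conservation of probability
mass).

## Pass/fail criteria as configuration

A procedure verdict is a conjunction of per-metric criteria. The built-in
default reproduces the deployed rules: TAD ≤ 20 mm, center–center or
center–inferior placement, no cortical breach, at most 3 K-wire attempts;
CL2 adds no reamer breach, an appropriate plate angle and a bicortical
shaft screw. Failure is strictly *beyond* each bound, so boundary values
(TAD exactly 20 mm, exactly 3 attempts) pass. Fluoroscopy time, radiograph
count and total time are carried in the log but never affect the verdict.

The complete deployed CL2 criterion list is not publicly enumerated, so
criteria are data rather than code: `load_ruleset()` reads a YAML rule set
(the shipped `inst/extdata/default_ruleset.yaml` is test-verified
equivalent to the built-in default), unknown metrics and malformed entries
are rejected with their entry index, and duplicate entries for one metric
all apply. There is no weighting or partial credit — the chart consumes
only the binary verdict.

## The synthetic cohort generator

No raw learner data are public, so the generator produces cohorts with the
*structure* the analysis assumes; it targets structural, not numerical,
fidelity.

* **Learning curve.** Failure probability decays exponentially with
  cumulative experience, `p(t) = asymptotic + (initial − asymptotic)
  e^{−t/τ}` — the simplest monotone model consistent with learning-curve
  behaviour. Parameters are configuration, not code.
* **Archetypes.** The default mixture is two equally weighted profiles
  chosen once as plausible for first-year residents: a *persistent* learner
  (initial failure 0.45, asymptotic 0.04 — comfortably below the adequate
  rate — τ = 12 procedures, budget 150 procedures, i.e. enough for the
  whole program) and a *non-persistent* learner (initial 0.65, asymptotic
  0.20 — above the unacceptable rate — τ = 35, budget 60 procedures,
  modelling learners who do not return for later training days).
* **Career outcome.** Drawn Bernoulli conditional *only* on the program
  verdict, with default stay probabilities 13/14 after a pass and 9/18
  after a failure — the minimal structure able to reproduce the observed
  2×2 association. Richer confounding can be expressed through profile
  mixtures but is off by default.
* **Metrics.** Per-procedure metrics are sampled constructively: draw from
  level-specific distributions (TAD centred on 13 mm among passes, times
  and imaging counts loosely matched to reported level summaries), then
  re-assess with the rule engine and redraw until the logged verdict is
  reproduced, with a bounded retry that turns an inconsistent custom rule
  set into an explicit generation error.

What the generator does **not** emulate: correlation between metrics and
the learning curve (a learner close to signalling draws metrics from the
same conditional distributions as a novice), session/day structure, fatigue
or forgetting between sessions, and any confounding between persistence and
career outcome beyond the verdict. Passing tests therefore show that the
pipeline's statistics are internally consistent under these assumptions,
not that real cohorts satisfy them.

Everything is seed-deterministic: identical configuration and seed give
byte-identical procedure logs, and the pipeline writes a manifest with the
seed and an MD5 hash of the configuration.

## Cohort diagnostics

`diagnostic_measures` reads the pass/fail × stayed/left table as a
diagnostic test: PPV and NPV along the verdict rows, sensitivity and
specificity down the outcome columns, exact rational point estimates, and
Wilson score intervals by default — on the observed `(13, 1, 9, 9)` table
Wilson reproduces the published NPV (29–71) and sensitivity (39–77)
intervals to the whole percent, which Wald and Clopper–Pearson do not.
Clopper–Pearson is available as an option. Near a proportion of 1 interval
conventions diverge across software by about a percentage point (the
Wilson PPV upper bound here is 99, and the specificity upper bound 98); the
interval method is therefore carried in the output metadata. Fisher's exact
test uses the two-sided probability-mass ordering (conventions differ; the
suite pins this one against brute-force enumeration over all tables with
the observed margins), and the chi-square test defaults to no continuity
correction with a toggle. Group summaries report mean with a t-based 95%
interval and median with range; a single-learner group yields an undefined
interval and an empty group a row of missing values rather than an error.

## Problem sizes and degenerate inputs

The test suite exercises the DP–Monte-Carlo agreement at 10⁵ replicates per
rate, cohort parameter recovery with 2,000 learners per failure rate
(empirical program-pass fraction within three binomial standard errors of
the exact value), and 10³ generator/assessor round-trips — sizes at which
binomial noise is far below the effects being checked while the whole suite
stays fast. Degenerate inputs are defined behaviour: an empty outcome
sequence is an empty trajectory with no signal; a failure at score 0 stays
at 0; true failure rates of exactly 0 and 1 give signal probabilities of
exactly 1 (mass concentrated at procedure 13) and 0; a cohort in which
every learner passes makes the predictive values undefined, which the
pipeline reports as a note rather than a failure.

## Known limitations

* Operating characteristics assume independent Bernoulli outcomes at a
  fixed rate; learning-curve (non-stationary) behaviour is exercised by
  simulation only. No steady-state average-run-length theory is included —
  the finite-horizon DP is exact and sufficient for capped programs.
* No risk adjustment and no non-binary outcome charts.
* The rule engine classifies from pre-computed metrics; it does not compute
  TAD from imaging geometry.
* The generator's archetype parameters are plausible defaults, not fitted
  values; conclusions about real cohorts require re-estimating them.
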