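---
title: "Methods: a Markov cohort cost-effectiveness model for PTSD treatments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort cost-effectiveness model for PTSD treatments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptsdcea)
```

## The decision problem

Three treatments for veterans with posttraumatic stress disorder are
compared from a health-care organization perspective: Transcendental
Meditation (TM), Prolonged Exposure therapy (PE) and a PTSD health
education control (HE). Each was delivered as 12 sessions over 12 weeks in
a three-arm randomized trial; the clinically relevant effectiveness
outcome is the proportion of participants with a clinically significant
improvement (a reduction of at least 10 points on the
Clinician-Administered PTSD Scale) at the 12-week assessment: 32% (HE),
61% (TM) and 42% (PE).

Because trial follow-up stops at three months, longer-run costs and
quality-adjusted life years (QALYs) are extrapolated with a three-state
Markov cohort model: *clinically improved* (CI), *not clinically
improved* (NI), and *dead* (absorbing). Cycles are three months long
(matching the trial assessment interval); the horizon is 20 cycles, i.e.
five years.

## Model structure and parameters

The cohort enters split by the trial response rate: a fraction
`p_respond` starts in CI, the remainder in NI. Each subsequent cycle
allows relapse (CI to NI, 6% annually), remission of non-responders
seeking other treatment or improving spontaneously (NI to CI, 10%
annually), and all-cause death. Background annual mortality is 0.0045 for
improved patients and 0.0059 — the background rate times a relative risk
of 1.32 associated with PTSD — for unimproved patients.

Annual probabilities are converted to per-cycle probabilities with the
constant-hazard formula `q = 1 - (1 - p)^(1/4)`, so four composed cycles
reproduce the annual probability exactly. Dividing by four instead would
change only the fourth decimal at these magnitudes but does not compose
consistently.

State rewards per cycle are occupancy × utility × 0.25 years for QALYs
(utilities 0.63 for CI, 0.54 for NI, 0 for dead) and occupancy × annual
health-care cost × 0.25 for costs ($7,855/yr for CI, $12,154/yr for NI,
$0 for dead — the dead state carrying zero utility and zero cost is the
universal cohort-CEA convention). The one-time intervention cost ($492
HE, $1,504 TM, $2,822 PE) enters undiscounted at time zero, since
treatment is delivered during the first 12 weeks. An annual discount of
3% applies to costs and QALYs accruing from cycle 5 onward. At a
willingness to pay (WTP) of $50,000 per QALY, net monetary benefit is
`NMB = WTP × ΔQALYs − ΔCost`.

All inputs, their sensitivity ranges and their sampling distributions are
bundled as `table1_default_config()` and as the editable YAML file
`inst/extdata/table1_ptsd.yaml`.

## Within-cycle conventions and calibration

The published analysis was produced with commercial decision-tree
software whose within-cycle conventions are not part of the printed
inputs. Five conventions can plausibly differ without contradicting the
printed inputs, and each is an explicit flag in `model_conventions()`:

* **Transition order** — whether state-specific death is applied before
  or after the relapse/remission split within a cycle (`death-first`
  default).
* **Mortality start** — whether background mortality already thins the
  initial 12-week response split (cycle 1) or enters at the first
  transition (cycle 2). Default: cycle 1.
* **Half-cycle correction** — trapezoidal averaging of start- and
  end-of-cycle occupancy. Default: off.
* **Discount stepping** — a factor constant within each model year
  (`stepwise`, default) versus continuous per-cycle compounding.
* **Cost accrual start** — the first cycle in which state health-care
  costs accrue. Default: cycle 2; QALYs always accrue from cycle 1.

`calibrate_conventions()` reruns the deterministic model under all 32
combinations and ranks them by maximum relative error against the
published per-arm QALYs and total costs (`table2_reference()`). The
package defaults are the calibrated optimum, which reproduces all six
benchmark values within ±1%.

The cost-accrual flag deserves a note. With health-care costs accruing in
all 20 cycles, every convention combination leaves total costs 5–7% above
the published figures while QALYs fit well; the discrepancy is almost
exactly one first-cycle cost accrual for every arm. Starting health-care
cost accrual at cycle 2 — i.e. treating routine care during the 12-week
treatment period as subsumed in the intervention cost — resolves all
three arms simultaneously. We therefore model it as a convention flag and
let the calibration decide, rather than presenting either choice as
documented fact.

## Sensitivity analyses

**One-way tornado.** `one_way_tornado()` reruns the full model with each
parameter at its printed low and high values (all others at base) and
records the incremental NMB of a chosen arm pair. Parameters without a
range (the fixed relapse and remission rates) are skipped with a warning.
For TM vs PE the two health-state utilities produce the widest bars, and
every endpoint remains positive.

**Distribution fitting.** For the probabilistic sensitivity analysis
(PSA), beta and gamma distributions are moment-matched so that draws have
mean equal to the base value and standard deviation `(high − low)/3.92` —
the printed range read as a central 95% interval, the conventional choice
when a published table gives ranges without naming their meaning (here:
trial confidence intervals for the response rates, ±20% for costs, ±10%
for mortality). Triangular distributions take (min = low, mode = base,
max = high) as hard bounds. Fixed parameters are point masses.

**PSA design.** Each of 1000 draws samples every non-fixed parameter once
and shares it across arms (utilities, health-care costs and mortality are
population quantities; sharing is the standard design and is what makes
dominance tallies meaningful). Draws are independent across parameters —
the source provides no correlation structure. Beta and triangular
samplers cannot leave their supports; a redraw guard for out-of-range
probabilities is retained for safety and its trigger count logged.
`run_psa()` is fully reproducible given its seed (default 20250101,
n = 1000 matching the published simulation count). Reported tallies:
the fraction of draws in which TM is cheaper and more effective than
(dominates) PE, the fraction in which PE is more effective but not worth
its extra cost at the analysis WTP, and the fraction in which each arm
maximizes NMB among all three. `ceac()` traces the acceptability curve
over a WTP grid with the same optimality rule (ties broken by lower cost,
then arm name — determinism for testing).

Exact replication of the published PSA percentages is impossible in
principle: the original seed and distribution parameterization are not
stated, so agreement is expected only to Monte-Carlo and
parameterization tolerance (a few percentage points at n = 1000), which
is what the test suite asserts.

## Verification oracles and synthetic data

Two independently written oracles check the cohort engine:

* `expectation_oracle()` recomputes total discounted cost and QALYs by
  explicit per-cycle matrix–vector expectation with its own rate
  conversion, matrix composition and discount arithmetic. The test suite
  asserts agreement with `run_cohort()` to 1e-9 relative on 1,000 random
  configurations with randomized convention flags.
* `microsimulate()` walks individual patients through the state process
  with per-cycle categorical draws under identical reward rules; its
  means are unbiased for the cohort values and the suite checks agreement
  within three standard errors at n = 200,000 per arm, plus the 1/√n
  scaling of the standard errors. Each individual consumes a dedicated
  row of a pre-drawn uniform matrix derived from the master seed, making
  trajectories reproducible independent of evaluation order.

`simulate_trial()` emulates the structure of the source trial — binomial
responder counts at given true rates for 68/68/67 randomized participants
(the total of 203 split near-evenly; per-arm counts are not published) —
with Wilson score 95% intervals, whose ~95% coverage is itself tested.
`apply_trial()` feeds simulated proportions back into a configuration,
so every stage of the pipeline can be exercised without any external
data.

What the synthetic machinery does *not* emulate: individual symptom-score
trajectories, dropout, treatment re-entry, age-dependent mortality,
time-varying utilities or costs, or correlation between parameters.
Passing tests therefore demonstrate internal correctness of the model
arithmetic and reproduction of the published aggregate results, not
validity of the published inputs themselves.

## Numerical choices and problem sizes

Tolerances: occupancy conservation at 1e-12 per cycle; oracle
equivalence at 1e-9 relative; sampler moments at 0.5% (mean) and 2% (sd)
over 10^6 draws. Currency figures are rounded to whole dollars and QALYs
to two decimals only in display methods; all machine-readable outputs
carry full precision (the published NMB of $6,656 for TM vs PE is itself
only reproducible from unrounded internals — rounding ΔQALYs to 0.06
first would give $6,748). ICERs are reported only when the cost and
effect differences share a sign; dominance is reported otherwise.

The default test suite runs the full 32-combination calibration, a
1000-draw PSA, 1,000 random-configuration oracle comparisons and
200,000-patient microsimulations per arm; the whole suite completes in
well under a minute on a single CPU, and the acceptance script in a few
seconds.

## Known limitations

The model inherits every limitation of its inputs: effectiveness from a
single trial of mostly male veterans, health-care costs and utilities
from external literature rather than trial-linked utilization, a single
annual mortality rate per state, and a five-year horizon. The
cost-accrual-start convention is a calibrated inference about the
original implementation, not a documented fact. Budget projections via
`scale_savings()` are deliberately linear and carry no uncertainty.
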