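# ptsdcea

A Markov cohort cost-effectiveness model comparing three treatments for
posttraumatic stress disorder (PTSD) in veterans — Transcendental
Meditation (TM), Prolonged Exposure therapy (PE) and a PTSD health
education control (HE) — from a health-care organization perspective.

Trial follow-up for these treatments stops at 12 weeks, so the package
extrapolates costs and quality-adjusted life years (QALYs) over a
five-year horizon with a three-state Markov cohort model: clinically
improved (CI), not improved (NI), and dead (absorbing), in 20 three-month
cycles. Cohorts enter split by the trial response rate (32% HE / 61% TM /
42% PE); cycles apply annual relapse (6%), remission (10%) and
state-specific background mortality (0.0045 CI, 0.0059 NI) converted to
per-cycle probabilities by the constant-hazard formula
`q = 1 − (1 − p)^¼`. Rewards are utilities (0.63 CI / 0.54 NI) and annual
health-care costs ($7,855 CI / $12,154 NI), discounted 3% annually from
cycle 5. Comparisons are summarized as incremental cost-effectiveness
ratios (ICER = ΔCost/ΔQALYs, with dominance verdicts when the signs
disagree) and net monetary benefit (NMB = WTP × ΔQALYs − ΔCost) at a
willingness to pay of $50,000/QALY.

The package covers:

* parameter definition, validation, YAML/JSON (de)serialization and a
  bundled base-case configuration (`table1_default_config()`,
  `inst/extdata/table1_ptsd.yaml`);
* the cohort engine (`run_cohort()`, `run_model()`) with explicit
  within-cycle convention flags and a calibration routine
  (`calibrate_conventions()`) that grid-searches them against the
  published benchmark results;
* incremental analysis (`incremental_analysis()`, `optimal_strategy()`,
  `efficiency_frontier()`, `cost_per_responder()`);
* one-way tornado analysis (`one_way_tornado()`), probabilistic
  sensitivity analysis with moment-matched beta/gamma and triangular
  samplers (`fit_sampler()`, `run_psa()`) and acceptability curves
  (`ceac()`);
* verification oracles — an independent matrix-expectation
  implementation (`expectation_oracle()`) and an individual-level
  microsimulation (`microsimulate()`) — plus a synthetic binomial trial
  generator (`simulate_trial()`).

## Worked example

```r
library(ptsdcea)
cfg <- table1_default_config()
print(cea_report(cfg))
```

```
Per-arm results (5-year horizon):
 arm p_respond qalys intervention_cost healthcare_cost total_cost
  HE      0.32  2.69               492           45576      46068
  TM      0.61  2.77              1504           41877      43381
  PE      0.42  2.72              2822           44300      47122
 cost_per_responder
               1538
               2466
               6719

Incremental comparisons (WTP $50,000/QALY):
 intervention reference delta_cost delta_qalys delta_response  verdict
           TM        HE      -2686        0.09           0.29 dominant
           TM        PE      -3741        0.06           0.19 dominant
           PE        HE       1055        0.03           0.10     icer
 icer_per_qaly icer_per_responder  nmb
            NA                 NA 7040
            NA                 NA 6593
         35127              10547  447

Optimal strategy: TM
```

Reading the output: TM accrues the most QALYs (2.77/person over five
years) *and* the lowest total cost, because the higher health-care costs
of non-response outweigh its intervention-cost premium over HE — so TM
dominates both comparators (no ICER is defined for a dominant strategy;
its NMB of ~$6,600 vs PE is the monetary value of the health gained plus
the cost saved). PE vs HE involves a genuine trade-off: about $35,100 per
QALY gained, or ~$10,500 per additional responder, below the
$50,000/QALY threshold.

Sensitivity analyses:

```r
tor <- one_way_tornado(cfg, c("TM", "PE"))   # utilities dominate the chart
psa <- run_psa(cfg, n_draws = 1000, seed = 20250101)
psa_tallies(psa, c("TM", "PE"))              # dominance/optimality fractions
head(ceac(psa, seq(0, 150000, 5000)))        # acceptability curves
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/ptsd-cea base --config inst/extdata/table1_ptsd.yaml --out out/
Rscript inst/cli/ptsd-cea psa  --config inst/extdata/table1_ptsd.yaml --n-draws 1000 --out out/
Rscript inst/cli/ptsd-cea calibrate --config inst/extdata/table1_ptsd.yaml --out out/
```

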