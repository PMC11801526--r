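arms:
  HE:
    p_respond:
      base: 0.32
      dist: beta
      role: probability
      low: 0.256
      high: 0.384
    intervention_cost:
      base: 492.0
      dist: triangular
      role: cost_one_time
      low: 394.0
      high: 590.0
  TM:
    p_respond:
      base: 0.61
      dist: beta
      role: probability
      low: 0.49
      high: 0.73
    intervention_cost:
      base: 1504.0
      dist: triangular
      role: cost_one_time
      low: 1203.0
      high: 1805.0
  PE:
    p_respond:
      base: 0.42
      dist: beta
      role: probability
      low: 0.336
      high: 0.504
    intervention_cost:
      base: 2822.0
      dist: triangular
      role: cost_one_time
      low: 1605.0
      high: 3386.0
shared:
  relapse_annual:
    base: 0.06
    dist: fixed
    role: annual_rate
  remission_annual:
    base: 0.1
    dist: fixed
    role: annual_rate
  mortality_improved_annual:
    base: 0.0045
    dist: beta
    role: annual_rate
    low: 0.0036
    high: 0.0054
  mortality_not_improved_annual:
    base: 0.0059
    dist: beta
    role: annual_rate
    low: 0.0047
    high: 0.0071
  utility_improved:
    base: 0.63
    dist: beta
    role: utility
    low: 0.5
    high: 0.76
  utility_not_improved:
    base: 0.54
    dist: beta
    role: utility
    low: 0.43
    high: 0.65
  hc_cost_improved_annual:
    base: 7855.0
    dist: gamma
    role: cost_annual
    low: 6284.0
    high: 9426.0
  hc_cost_not_improved_annual:
    base: 12154.0
    dist: gamma
    role: cost_annual
    low: 9723.0
    high: 14585.0
policy:
  cycle_length_years: 0.25
  n_cycles: 20
  annual_discount_rate: 0.03
  discount_start_cycle: 5
  wtp_per_qaly: 50000.0
  reference_arm_pairs:
  - - TM
    - HE
  - - TM
    - PE
  - - PE
    - HE
conventions:
  transition_order: death-first
  mortality_start_cycle: 1
  half_cycle: no
  discount_method: stepwise
  cost_start_cycle: 2
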