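# Default parameter set: five school-based caries prevention strategies,
# South African public healthcare payer perspective, ZAR at 2022 prices.
# Cost SDs left out are imputed as 10% of the mean at load time.
model:
  cohort_size: 10000
  start_age: 5
  exit_age: 15
  n_cycles: 10
  discount_rate: 0.05
  prob_untreated: 0.7
  prob_recurrence: 0.188
  dmft_growth: 0.0059
  sugar_slope: 0.0128
  sugar_reduction: 30
  screening_cost: 525.61
  wtp: 38500
  effect_mechanism: dmft
  sugar_mechanism: slope
  exit_first: true
interventions:
- name: APF-Gel
  annual_cost_mean: 193.73
  effect_mean: 21
  effect_sd: 4
  requires_screening: true
- name: Fissure sealant
  annual_cost_mean: 59.71
  effect_mean: 50
  effect_sd: 8
  requires_screening: true
- name: ART
  annual_cost_mean: 89.24
  effect_mean: 72
  effect_sd: 25
  requires_screening: true
- name: Tooth brushing
  annual_cost_mean: 548.33
  annual_cost_sd: 544.29
  effect_mean: 60
  effect_sd: 47
  requires_screening: true
- name: Sugar reduction
  annual_cost_mean: 1.25
  effect_mean: 31.89
  effect_sd: 0.18
  requires_screening: false
  is_sugar_policy: true
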