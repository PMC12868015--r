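name: small_1_20mm
econ:
  discount_rate: 0.03
  wtp: 100000.0
  horizon_cycles: 5
  cycle_length_years: 1.0
  annualization: linear
variant:
  lr_cost_mode: one_time_on_entry
  dr_cost_mode: per_cycle
  event_timing: entry_cycle
  dead_accrues_routine: no
  mortality_source_states: all_alive
bca:
  name: bca
  procedure_cost:
    base_value: 2501.0
    unit: usd
    dist:
      kind: gamma
      a: 25.020003999999997
      b: 99.960015993602553
  complication_prob:
    base_value: 0.024
    unit: probability
    dist:
      kind: beta
      a: 5.0
      b: 201.0
  complication_cost:
    base_value: 817.0
    unit: usd
    dist:
      kind: gamma
      a: 438.848783694937538
      b: 1.861689106487148
      group: complication_cost
  treatment_disutility:
    base_value: 0.02
    unit: utility
    dist:
      kind: point
      a: 0.02
  complication_disutility:
    base_value: 0.05
    unit: utility
    dist:
      kind: point
      a: 0.05
  p_local_annual:
    base_value: 0.0086
    unit: probability_per_year
    dist:
      kind: beta
      a: 8.0
      b: 186.0
      per_years: 5.0
  p_distant_annual:
    base_value: 0.0023
    unit: probability_per_year
    dist:
      kind: beta
      a: 2.0
      b: 192.0
      per_years: 4.5
  p_mortality_annual:
    base_value: 0.0073
    unit: probability_per_year
    dist:
      kind: beta
      a: 7.0
      b: 187.0
      per_years: 5.0
  routine_cost_increment:
    base_value: 0.0
    unit: usd
    dist:
      kind: point
      a: 0.0
bcs:
  name: bcs
  procedure_cost:
    base_value: 18859.0
    unit: usd
    dist:
      kind: gamma
      a: 24.997348956816374
      b: 754.440002121003204
  complication_prob:
    base_value: 0.1432
    unit: probability
    dist:
      kind: sum
      components:
      - kind: beta
        a: 266.0
        b: 17284.0
        target: 0.015
      - kind: beta
        a: 1592.0
        b: 15958.0
        target: 0.11
      - kind: beta
        a: 418.0
        b: 22583.0
        target: 0.0182
  complication_cost:
    base_value: 817.0
    unit: usd
    dist:
      kind: gamma
      a: 438.848783694937538
      b: 1.861689106487148
      group: complication_cost
  treatment_disutility:
    base_value: 0.1
    unit: utility
    dist:
      kind: point
      a: 0.1
  complication_disutility:
    base_value: 0.05
    unit: utility
    dist:
      kind: point
      a: 0.05
  p_local_annual:
    base_value: 0.0064
    unit: probability_per_year
    dist:
      kind: beta
      a: 469.0
      b: 5393.0
      per_years: 5.0
      frac: 0.4
      group: bcs_recurrence
  p_distant_annual:
    base_value: 0.0096
    unit: probability_per_year
    dist:
      kind: beta
      a: 469.0
      b: 5393.0
      per_years: 5.0
      frac: 0.6
      group: bcs_recurrence
  p_mortality_annual:
    base_value: 0.0091
    unit: probability_per_year
    dist:
      kind: beta
      a: 265.0
      b: 28781.0
  routine_cost_increment:
    base_value: 0.0
    unit: usd
    dist:
      kind: point
      a: 0.0
shared:
  routine_annual_cost:
    base_value: 36351.0
    unit: usd
    dist:
      kind: gamma
      a: 68.222870429615114
      b: 532.827184946768966
  local_recurrence_cost:
    base_value: 36351.0
    unit: usd
    dist:
      kind: gamma
      a: 68.222870429615114
      b: 532.827184946768966
  advanced_disease_cost:
    base_value: 153049.0
    unit: usd
    dist:
      kind: gamma
      a: 7.882153586305932
      b: 19417.155264000419265
  u_first_year:
    base_value: 0.696
    unit: utility
    dist:
      kind: normal
      a: 0.696
      b: 0.029
  u_subsequent:
    base_value: 0.779
    unit: utility
    dist:
      kind: normal
      a: 0.779
      b: 0.038
  u_local:
    base_value: 0.779
    unit: utility
    dist:
      kind: normal
      a: 0.779
      b: 0.038
  u_distant:
    base_value: 0.685
    unit: utility
    dist:
      kind: normal
      a: 0.685
      b: 0.029
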