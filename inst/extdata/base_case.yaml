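# Base-case configuration: 47-year-old, 30 annual cycles, 3% discount.
strategies:
  - name: IMPT
    p_eradicate: 0.9
    cost_radiotherapy: 50000
    cost_chemo: 5000
  - name: IMRT
    p_eradicate: 0.73
    cost_radiotherapy: 12000
    cost_chemo: 5000
disease:
  relapse_schedule:
    - {from_year: 1, to_year: 3, prob: 0.1}
    - {from_year: 4, to_year: 5, prob: 0.05}
    - {from_year: 6, to_year: 10, prob: 0.01}
  p_cancer_death: 0.3
  utilities:
    no_cancer: 0.94
    with_cancer: 0.47
    first_year: 0.47
    death: 0
  costs:
    followup_per_year: 1000
    palliative_per_year: 5000
settings:
  start_age: 47
  horizon: auto
  discount_rate: 0.03
  life_expectancy_endpoint: 77
wtp: [30828, 50000, 100000]
psa:
  n_iterations: 50000
distributions:
  - {param: p_eradicate_a, kind: beta, mean: 0.9, ci90: [0.833, 0.957]}
  - {param: p_eradicate_b, kind: beta, mean: 0.73, ci90: [0.665, 0.792]}
  - {param: c_radiotherapy_a, kind: normal, mean: 50000, ci90: [37258.3, 62775.4]}
  - {param: c_radiotherapy_b, kind: normal, mean: 12000, ci90: [10723.2, 13287.5]}
  - {param: c_chemo, kind: normal, mean: 5000, ci90: [3710.4, 6284.7]}
  - {param: c_followup, kind: normal, mean: 1000, ci90: [872.1, 1127.8]}
  - {param: c_palliative, kind: normal, mean: 5000, ci90: [3724.0, 6269.1]}
  - {param: u_no_cancer, kind: beta, mean: 0.94, ci90: [0.822, 1.0]}
  - {param: u_with_cancer, kind: beta, mean: 0.47, ci90: [0.343, 0.598]}
  - {param: p_cancer_death, kind: beta, mean: 0.3, ci90: [0.237, 0.365]}
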