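# Default study configuration: three enteral nutrition-support arms
# (percutaneous endoscopic gastrostomy, nasogastric tube feeding, oral
# nutritional supplements), 63 subjects each, calibrated to the published
# group summaries of the source trial. Probability vectors are given as
# counts out of 63 divided out on read; category orders are fixed:
#   weight_category_probs: gain / unchanged / loss
#   response_probs:        CR / PR / SD / PD
#   stage_probs:           IIA / IIB / III / IVA / IVB
#   ecog_probs:            "0-1" / "2"
seed: 20180515
arms:
  - arm_label: PEG
    n_subjects: 63
    weight_change_mean: -1.4
    weight_change_sd: 4.4
    weight_category_probs: [18, 7, 38]
    albumin_ge35_prob: 0.98412698412698
    crp_lt15_prob: 0.60317460317460
    lymph_ge1_prob: 0.17460317460317
    response_probs: [50, 12, 1, 0]
    lrfs_1yr: 0.883
    os_1yr: 0.886
    cost_means:
      radiotherapy: 10086.04
      chemotherapy: 695.95
      nutrition_support: 1120.28
      antibiotics_emergencies: 332.98
    hospital_days_mean: 11.3
    age_range: [44, 87]
    sex_male_prob: 0.74603174603175
    stage_probs: [2, 5, 38, 18, 0]
    ecog_probs: [63, 0]
    baseline_weight_mean: 58.7
    baseline_weight_sd: 9.0
  - arm_label: NTF
    n_subjects: 63
    weight_change_mean: -2.1
    weight_change_sd: 3.3
    weight_category_probs: [8, 26, 29]
    albumin_ge35_prob: 0.88888888888889
    crp_lt15_prob: 0.42857142857143
    lymph_ge1_prob: 0.11111111111111
    response_probs: [36, 21, 2, 4]
    lrfs_1yr: 0.786
    os_1yr: 0.831
    cost_means:
      radiotherapy: 8519.56
      chemotherapy: 1362.66
      nutrition_support: 732.56
      antibiotics_emergencies: 1267.82
    hospital_days_mean: 28.7
    age_range: [40, 75]
    sex_male_prob: 0.85714285714286
    stage_probs: [2, 0, 42, 17, 2]
    ecog_probs: [62, 1]
    baseline_weight_mean: 58.0
    baseline_weight_sd: 9.0
  - arm_label: ONS
    n_subjects: 63
    weight_change_mean: -3.0
    weight_change_sd: 5.4
    weight_category_probs: [7, 21, 35]
    albumin_ge35_prob: 0.80952380952381
    crp_lt15_prob: 0.39682539682540
    lymph_ge1_prob: 0.04761904761905
    response_probs: [34, 23, 4, 2]
    lrfs_1yr: 0.768
    os_1yr: 0.812
    cost_means:
      radiotherapy: 8377.22
      chemotherapy: 2248.82
      nutrition_support: 757.65
      antibiotics_emergencies: 1073.23
    hospital_days_mean: 28.3
    age_range: [44, 80]
    sex_male_prob: 0.79365079365079
    stage_probs: [4, 3, 28, 25, 3]
    ecog_probs: [62, 1]
    baseline_weight_mean: 58.4
    baseline_weight_sd: 9.0
# Decision-model defaults. One-time strategy costs are the observed mean
# total healthcare costs from diagnosis to 6 months post-treatment, in USD
# (exchange rate 1 USD = 6.37 CNY). Long-run state costs and the mortality
# rates of the relapse state are package defaults (see the methods
# vignette); survival-derived transition inputs come from the arm profiles.
markov:
  states: [disease_free, relapse, death]
  cycle_length: 1
  horizon_cycles: 38
  discount_rate: 0.03
  utilities: [0.80, 0.53, 0.0]
  background_mortality: 0.01
  relapse_mortality: 0.5
  state_costs: [2000, 5000, 0]
  one_time_cost:
    PEG: 16918.55
    NTF: 19123.92
    ONS: 18399.01
cea:
  wtp_grid: [0, 5000, 10000, 15000, 20000, 25000, 30000, 35000, 40000, 45000, 50000]
  headline_thresholds: [10000, 50000]
  cost_effective_threshold: 33962
  psa_draws: 10000
  usd_per_cny: 6.37
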