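n_young: 21
n_old: 20
group_means:
  young:
    TRT: 62.76
    WST: 32.05
    OperationSpan: 59.62
    Verbal_learning: 65.24
    Recall: 0.05
    Recognition: 14.71
    RT_word: 302.86
    RT_freq: 164.1
    CTMT_1_2: 3.71
    CTMT_1_3: 5.02
    CTMT_1_4: 0.23
    CTMT_1_5: 11.04
    Distraction_sensitivity: 20.95
    y_median: 4.4
  old:
    TRT: 42.2
    WST: 34.4
    OperationSpan: 41.89
    Verbal_learning: 57.3
    Recall: 1.45
    Recognition: 13.8
    RT_word: 180.25
    RT_freq: 245.65
    CTMT_1_2: -3.0
    CTMT_1_3: 5.8
    CTMT_1_4: -5.0
    CTMT_1_5: 20.95
    Distraction_sensitivity: 28.75
    y_median: 2.5
group_sds:
  young:
    TRT: 13.21
    WST: 2.2
    OperationSpan: 9.16
    Verbal_learning: 6.39
    Recall: 0.67
    Recognition: 0.56
    RT_word: 153.2
    RT_freq: 131.98
    CTMT_1_2: 6.37
    CTMT_1_3: 6.16
    CTMT_1_4: 6.83
    CTMT_1_5: 7.86
    Distraction_sensitivity: 6.54
    y_median: 2.26
  old:
    TRT: 10.76
    WST: 2.22
    OperationSpan: 17.8
    Verbal_learning: 9.48
    Recall: 2.04
    Recognition: 1.47
    RT_word: 89.84
    RT_freq: 241.06
    CTMT_1_2: 13.39
    CTMT_1_3: 9.58
    CTMT_1_4: 13.1
    CTMT_1_5: 14.75
    Distraction_sensitivity: 8.34
    y_median: 1.93
latent_loadings:
  TRT: 0.65
  WST: 0.15
  OperationSpan: 0.6
  Verbal_learning: 0.45
  Recall: 0.1
  Recognition: 0.3
  RT_word: -0.15
  RT_freq: -0.1
  CTMT_1_2: -0.25
  CTMT_1_3: -0.25
  CTMT_1_4: -0.25
  CTMT_1_5: -0.55
  Distraction_sensitivity: -0.3
response_loading: 0.75
response_bounds:
- 0.0
- 7.0
floor_mass: 0.15
n_ospan_missing_old: 0
recall_convention: t7_minus_t5
seed: 1
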