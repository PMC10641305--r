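# Full-size synthetic scenario: the complete tagged cohort
# (1337 + 4442 individuals across the two streams). Hierarchical fits at
# this size are substantially slower than the scaled default; load with
# read_scenario().
species: [BHC, CRC, STJ]
streams: [indian, todd]
n_occasions: 15
start_date: "2015-11-15"
interval_days: [48, 70]
entry_totals: [429, 664, 244, 3608, 195, 639]
entry_scale: 1.0
mu: [1.7, 1.4, 1.1]
beta: -0.5
covariate_effect: true
sigma2_t: 0.60
sigma2_j: [0.42, 0.44, 0.80]
sigma2_s: [0.64, 1.08]
sigma2_js: [1.33, 0.60, 1.50, 0.42, 1.28, 0.98]
detection_range: [0.18, 0.53]
seed: 42
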