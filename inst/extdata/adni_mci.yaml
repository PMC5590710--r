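# Example population parameters for a mild-cognitive-impairment (early AD)
# population: transformed MMSE, CDR-SB and ADAS-11 component scores
# (higher = worse cognition, rescaled by baseline standard deviation).
labels: [MMSE, CDRSB, ADAS11]
beta0: [0.0, 0.0, 0.0]
# annual rates of change (score units / year)
beta2: [0.079, 0.061, 0.055]
# random-intercept covariance (between-subject)
sigma_b:
  - [0.58, 0.30, 0.48]
  - [0.30, 0.71, 0.37]
  - [0.48, 0.37, 0.77]
# within-visit error covariance
sigma_eps:
  - [0.56, 0.07, 0.09]
  - [0.07, 0.57, 0.06]
  - [0.09, 0.06, 0.44]
effect:
  # treatment removes 25% of each annual rate of change
  reduction: 0.25
design:
  duration: 2        # years
  interval: 0.5      # biannual visits at 0, 0.5, ..., duration - 0.5
  allocation: 0.5
  alpha: 0.05
  target_power: 0.80
  sidedness: two_sided_chi2
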