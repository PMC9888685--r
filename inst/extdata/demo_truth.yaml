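# Reference generative truth for the synthetic multilevel cohort: two
# subgroups defined by z1 with opposite-signed focus effects, each moderated
# by a standardized tract-level contextual variable.
leaves:
  - condition: "z1 < 0.5"
    theta0: 1.0
    theta1: -0.6
    theta2: 0.15
  - condition: "z1 >= 0.5"
    theta0: 2.0
    theta1: 0.3
    theta2: -0.12
covariates:
  z1: {scale: continuous, min: 0, max: 1}
  z2: {scale: continuous, min: 0, max: 1}
  z3: {scale: continuous, min: 0, max: 1}
noise_sd: 0.25
censor_rate: 0.2
M: 100
w_mean: 0
w_sd: 1
"n": 2000
focus_prevalence: 0.5
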