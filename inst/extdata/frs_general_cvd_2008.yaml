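# Sex-specific 10-year general cardiovascular disease risk equation
# (lipid-based variant), transcribed Cox proportional-hazards coefficients.
# risk = 1 - s0 ^ exp(lp - mean_lp), lp = sum(beta * transformed covariate).
# Cholesterol betas expect mg/dL (declared below); callers holding mmol/L
# convert at 38.67 mg/dL per mmol/L.
version: general-cvd-2008-lipid-v1
units:
  cholesterol: mg/dL
  sbp: mmHg
male:
  ln_age: 3.06117
  ln_tc: 1.12370
  ln_hdl: -0.93263
  ln_sbp_untreated: 1.93303
  ln_sbp_treated: 1.99881
  smoker: 0.65451
  diabetes: 0.57367
  mean_lp: 23.9802
  s0: 0.88936
female:
  ln_age: 2.32888
  ln_tc: 1.20904
  ln_hdl: -0.70833
  ln_sbp_untreated: 2.76157
  ln_sbp_treated: 2.82263
  smoker: 0.52873
  diabetes: 0.69154
  mean_lp: 26.1931
  s0: 0.95012
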