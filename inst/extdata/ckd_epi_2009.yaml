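# CKD-EPI serum creatinine equation (2009), transcribed coefficients.
# eGFR = scale * min(Scr/kappa, 1)^alpha * max(Scr/kappa, 1)^exp_above
#        * age_base^age * sex_multiplier   [mL/min/1.73 m2]
# The race multiplier is intentionally not applied (all-Chinese cohort).
version: ckd-epi-2009-creatinine-v1
units:
  creatinine: mg/dL
common:
  scale: 141.0
  exp_above: -1.209
  age_base: 0.993
male:
  kappa: 0.9
  alpha: -0.411
  sex_multiplier: 1.0
female:
  kappa: 0.7
  alpha: -0.329
  sex_multiplier: 1.018
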