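# NTCP model-parameter registry, keyed by organ.
# Forward-evaluation parameter sets for the four functional-organ models
# plus an EUD/TCP set for the target.
hippocampus:
  complication: neurocognitive impairment
  model: lkb_eqd2_d40
  TD50_Gy: 14.88
  m: 0.54
  alpha_beta_Gy: 2
scalp:
  complication: acute grade 2 alopecia
  model: lkb_geud
  TD50_Gy: 22
  m: 0.54
  "n": 0.14
hpa:
  complication: endocrine dysfunction
  model: multivariate_parametric
  gamma: 0.56
  const: 3.13
  beta_age: -0.106
  beta_age2: 0.007
  beta_dose: -0.049
  t_years: 5
cochlea:
  complication: hearing loss
  model: logistic
  b0: -5.3
  b1: 0.085
tcp:
  # Illustrative target EUD/TCP parameters. No validated pediatric
  # medulloblastoma set is bundled; override for any quantitative use.
  model: niemierko_logistic
  eud_exponent_a: -10
  TCD50_Gy: 30
  gamma50: 2
  illustrative: true
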