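# CNS-MPO desirability breakpoints and triage cutoffs.
# Monotone specs: [lower, upper] -- 1 at/below lower, 0 at/above upper.
# Hump specs: [a, b, c, d] -- 0 outside (a, d), 1 inside [b, c].
mpo:
  clogp: {kind: monotone_decreasing, breakpoints: [3.0, 5.0]}
  clogd: {kind: monotone_decreasing, breakpoints: [2.0, 4.0]}
  mw: {kind: monotone_decreasing, breakpoints: [360.0, 500.0]}
  tpsa: {kind: hump, breakpoints: [20.0, 40.0, 90.0, 120.0]}
  hbd: {kind: monotone_decreasing, breakpoints: [0.5, 3.5]}
  pka: {kind: monotone_decreasing, breakpoints: [8.0, 10.0]}
triage:
  mpo_min: 4.0
  mpa_max: 70.0
  logs_min: -4.5
  mp_range: [30.0, 40.0]
  clogp_range: [2.0, 5.0]
logbb:
  coef_clogp: 0.152
  coef_psa: -0.0148
  intercept: 0.139
  readily_cutoff: 0.3
  poor_cutoff: -1.0
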