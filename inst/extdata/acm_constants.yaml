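# Aggregated canopy model coefficient set (canonical published vintage).
# Coefficients are data, not code: substitute an alternative vintage by
# pointing acm_constants() at another file. psi_d in MPa; r_tot in
# MPa s m2 mmol-1 equivalents of the original calibration.
version: "acm-classic-1.0"
coefficients:
  e1: 2.155
  e2: 0.0142
  e3: 217.9
  e4: 0.980
  e5: 0.155
  e6: 2.653
  e7: 4.309
  e8: 0.060
  e9: 1.062
  e10: 0.0006
  psi_d: -2.0
  r_tot: 1.0
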