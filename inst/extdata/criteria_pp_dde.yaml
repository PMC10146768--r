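# Worked criteria-derivation example for p-p'DDE.
# Baseline BAFs and lipid fractions as published; the freely dissolved
# fraction is supplied directly (0.0319) because the underlying POC/DOC
# water chemistry was never published and only the combined sorption
# term is recoverable. The unrounded model-predicted RfD (0.01271
# mg/kg/d) is used here: the published criterion (0.03 ug/L) was derived
# from it before significant-figure adoption.
chemical:
  id: "p-p'DDE"
  lg_kow: 6.76
  rfd: 0.01271
water:
  f_fd: 0.0319
trophic_levels:
  - {level: 2, f_l: 0.019, fcm: 1.000, bl_baf: 5.33e+7}
  - {level: 3, f_l: 0.026, fcm: 13.30, bl_baf: 5.18e+8}
  - {level: 4, f_l: 0.030, fcm: 1.128, bl_baf: 3.81e+7}
exposure:
  bw: 60.6
  di: 1.85
  fi2: 0.0126
  fi3: 0.0100
  fi4: 0.0075
  rsc: 0.2
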