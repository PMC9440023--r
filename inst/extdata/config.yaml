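scale_min: 0
scale_max: 10
full_score: 10
sd_denominator: n_minus_1
boundary_grouping: global
rounding:
  Mj: 2
  sd: 2
  Vj: 2
  Kj: 2
  Cs: 3
  Ca: 3
  Cr: 3
thresholds:
  response_rate_good: 70
  cr_acceptable: 0.7
  w_fair: 0.4
  w_complete: 0.5
  cr_band_lo: 0.5
  cr_band_hi: 0.75
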