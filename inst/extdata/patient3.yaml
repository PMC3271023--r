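patient_id: patient3
seed: 103
provenance: 'synthetic reconstruction: log-uniform draw in [0.5, 2], fixed seed'
multipliers:
  p_EGF: 0.674496665203885
  p_FGF: 0.545759096527129
  p_GCSF: 1.030720750692218
  p_GMCSF: 1.005027179148888
  p_HGF: 0.590894372223182
  p_IL10: 0.564306293710087
  p_IL1b: 0.912011511566202
  p_IL6: 0.653455835526026
  p_MIF: 0.522019995983844
  p_MMP9: 0.772551943947061
  p_PGE2: 0.935710669786149
  p_SCF: 0.743625084380259
  p_TGFb: 1.506482421078371
  p_TNFa: 1.568712806209836
  p_VEGF: 1.700567543776483
  r_EGF: 0.59901654843586
  r_FGF: 0.605028117879372
  r_GCSF: 0.742413350410489
  r_GMCSF: 0.816529476516157
  r_HGF: 0.795464522716868
  r_IL10: 0.637820744543819
  r_IL1b: 1.072819907423586
  r_IL6: 1.018537204778661
  r_MIF: 1.113590537488456
  r_PGE2: 1.069692242623107
  r_SCF: 1.720623597644829
  r_TGFb: 1.986339531258638
  r_TNFa: 1.829653791344776
  r_VEGF: 0.863067189805425

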