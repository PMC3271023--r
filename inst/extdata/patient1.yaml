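patient_id: patient1
seed: 101
provenance: 'synthetic reconstruction: log-uniform draw in [0.5, 2], fixed seed'
multipliers:
  p_EGF: 0.837636812660952
  p_FGF: 0.531318786815859
  p_GCSF: 1.337341612421669
  p_GMCSF: 1.244340048086832
  p_HGF: 0.706965366852449
  p_IL10: 0.757915893861878
  p_IL1b: 1.124850485458111
  p_IL6: 0.793847771150477
  p_MIF: 1.184291253481484
  p_MMP9: 1.065593441912079
  p_PGE2: 1.693011133007249
  p_SCF: 1.332143483411191
  p_TGFb: 1.379308518042234
  p_TNFa: 1.819155483918724
  p_VEGF: 0.939679831229921
  r_EGF: 1.133386134639265
  r_FGF: 1.559271541215301
  r_GCSF: 0.682185956457566
  r_GMCSF: 0.884745030740274
  r_HGF: 0.527492000953447
  r_IL10: 1.320810130362845
  r_IL1b: 1.883838022072862
  r_IL6: 0.672079593143813
  r_MIF: 1.250168884164426
  r_PGE2: 1.798305044046294
  r_SCF: 1.506749433946503
  r_TGFb: 0.551879464466611
  r_TNFa: 0.857860836348809
  r_VEGF: 0.878371063130948

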