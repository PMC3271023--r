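patient_id: patient2
seed: 102
provenance: 'synthetic reconstruction: log-uniform draw in [0.5, 2], fixed seed'
multipliers:
  p_EGF: 1.104396275467499
  p_FGF: 0.990181654095882
  p_GCSF: 1.481840814246254
  p_GMCSF: 1.057517401507558
  p_HGF: 0.564874806977898
  p_IL10: 0.895807058840466
  p_IL1b: 1.935445747167813
  p_IL6: 0.790386383986762
  p_MIF: 1.72244605457139
  p_MMP9: 0.892431813098484
  p_PGE2: 1.705388399485508
  p_SCF: 1.259924096376577
  p_TGFb: 1.547379739618636
  p_TNFa: 0.915856426401554
  p_VEGF: 1.148909172094728
  r_EGF: 1.760379821718436
  r_FGF: 1.335524535654684
  r_GCSF: 0.828168179966646
  r_GMCSF: 1.922532315898118
  r_HGF: 1.617172752321901
  r_IL10: 1.804264780078298
  r_IL1b: 1.170139277030096
  r_IL6: 1.065691083008705
  r_MIF: 1.180192978862201
  r_PGE2: 0.722211203024831
  r_SCF: 0.823444632746261
  r_TGFb: 0.57605034725683
  r_TNFa: 0.871135359189443
  r_VEGF: 0.88257211093127

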