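# Rat parameter set. Physiological rows are fixed literature values; the
# drug-specific rows carry the published scaled values (derived from mouse;
# build_species_params() regenerates and cross-checks them).
species: rat
physiology:
  BW: 0.25
  V_L: 0.078
  V_S: 0.0052
  V_Nb: 0.054
  Q_BL_i: 5.25
  Q_BL_o: 5.4
  Q_BS: 0.15
  H: 0.46
  fup: 0.06
  BPR: 0.84
  v_liver: 0.125
  v_spleen: 0.016
released:
  V_b: 0.67
  V_R: 0.2
  Q_BR: 0.007
  CL: 2.1               # nominal: in-vivo measured; in-vitro scaled 2.8
  CL_range: [2.1, 2.8]
  Bmax_L: 99
  KD_L: 0.6
  P_L: 1.5
  Bmax_S: 251.8
  KD_S: 0.63
  P_S: 0.33
conjugated:
  N_BL: 0.0002
  N_BS: 0.000004
  N_BR: 0.0
  K_NBL: 1.8
  K_NBS: 1000
  krel_b: 0.125
  krel_L: 0.016
  krel_S: 0.0063
  krel_R: 0.125
ivive:
  Clint: 48.7
  fuinc: 0.007
  hepatocellularity: 163
  liver_weight_g: 10
  Qh: 5.4
  in_vivo_blood_CL: 2.1
  in_vivo_plasma_CL: 1.8
  unconjugated_dose_mg_per_kg: 50
  unconjugated_plasma_AUC: 28
study:
  dose_mg_per_kg: [55, 110, 505]
  route: infusion
  infusion_duration_h: 0.5
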