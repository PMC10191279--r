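# Dog parameter set. Physiological rows are fixed literature values; the
# drug-specific rows carry the published scaled values (derived from mouse;
# build_species_params() regenerates and cross-checks them).
species: dog
physiology:
  BW: 10
  V_L: 0.048
  V_S: 0.0036
  V_Nb: 0.09
  Q_BL_i: 3.15
  Q_BL_o: 3.3
  Q_BS: 0.15
  H: 0.42
  fup: 0.06
  BPR: 0.97
  v_liver: 0.125
  v_spleen: 0.016
released:
  V_b: 0.59
  V_R: 0.19
  Q_BR: 0.0024
  CL: 1.5               # nominal: in-vivo measured; in-vitro scaled 2.5
  CL_range: [1.5, 2.5]
  Bmax_L: 85
  KD_L: 0.6
  P_L: 1.3
  Bmax_S: 217.8
  KD_S: 0.63
  P_S: 0.3
conjugated:
  N_BL: 0.0001
  N_BS: 0.000004
  N_BR: 0.0
  K_NBL: 1.6
  K_NBS: 1000
  krel_b: 0.125
  krel_L: 0.016
  krel_S: 0.0063
  krel_R: 0.125
ivive:
  Clint: 98.3
  fuinc: 0.007
  hepatocellularity: 169
  liver_weight_g: 384
  Qh: 3.3
  in_vivo_blood_CL: 1.5
  in_vivo_plasma_CL: 1.5
  unconjugated_dose_mg_per_kg: 12
  unconjugated_plasma_AUC: 8.9
study:
  dose_mg_per_kg: [12]
  route: infusion
  infusion_duration_h: 0.5
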