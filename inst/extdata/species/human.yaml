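# Human parameter set used for clinical projection. Physiological rows are
# fixed literature values; drug-specific rows carry the published scaled
# values (derived from mouse; build_species_params() regenerates and
# cross-checks them). CL comes from hepatocyte IVIVE: no in-vivo human data.
species: human
physiology:
  BW: 70
  V_L: 0.024
  V_S: 0.0027
  V_Nb: 0.074
  Q_BL_i: 1.23
  Q_BL_o: 1.3
  Q_BS: 0.066
  H: 0.45
  fup: 0.03
  BPR: 0.77
  v_liver: 0.125
  v_spleen: 0.016
released:
  V_b: 0.37
  V_R: 0.12
  Q_BR: 0.0013
  CL: 0.32              # scaled from human hepatocyte Clint of 15.5
  CL_range: [0.32]
  Bmax_L: 54
  KD_L: 0.6
  P_L: 0.83
  Bmax_S: 138
  KD_S: 0.63
  P_S: 0.19
conjugated:
  N_BL: 0.00004
  N_BS: 0.0000017
  N_BR: 0.0
  K_NBL: 1.0
  K_NBS: 1000
  krel_b: 0.125
  krel_L: 0.016
  krel_S: 0.0063
  krel_R: 0.125
ivive:
  Clint: 15.5
  fuinc: 0.007
  hepatocellularity: 120
  liver_weight_g: 1680
  Qh: 1.3
study:
  dose_mg_per_kg: [10]   # projection dose; regimen assumed bolus as in mouse
  route: bolus
  infusion_duration_h: 0
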