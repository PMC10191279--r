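# Mouse parameter set: the reference species. The released-API block was
# originally fitted to mouse biodistribution data; other species are derived
# from it by the interspecies scaling rules (see build_species_params()).
# Units: volumes L/kg, flows and clearances L/kg/h, Bmax/KD ng/mL, krel 1/h.
species: mouse
physiology:
  BW: 0.02
  V_L: 0.065
  V_S: 0.005
  V_Nb: 0.085
  Q_BL_i: 8.36          # = Q_BL_o - Q_BS
  Q_BL_o: 9.1
  Q_BS: 0.74
  H: 0.45               # hematocrit: standard physiology value, not model-fitted
  fup: 0.03
  BPR: 0.84
  v_liver: 0.125
  v_spleen: 0.016
released:
  V_b: 0.34
  V_R: 0.1
  Q_BR: 0.015
  CL: 1.0               # nominal; in-vitro scaled 2.0, in-vivo measured 2.3
  CL_range: [1.0, 2.0, 2.3]
  Bmax_L: 49.6
  KD_L: 0.6
  P_L: 0.76
  Bmax_S: 125.9
  KD_S: 0.63
  P_S: 0.17
conjugated:
  N_BL: 0.0003
  N_BS: 0.00002
  N_BR: 0.0
  K_NBL: 0.9
  K_NBS: 1000
  krel_b: 0.125
  krel_L: 0.016
  krel_S: 0.0063
  krel_R: 0.125         # set equal to krel_b
ivive:
  Clint: 36             # uL/min per 1e6 hepatocytes
  fuinc: 0.007
  hepatocellularity: 125  # 1e6 cells per g liver
  liver_weight_g: 1.25
  Qh: 9.1               # hepatic blood flow; liver-to-blood flow used as default
  in_vivo_blood_CL: 2.3
  in_vivo_plasma_CL: 2.0
  unconjugated_dose_mg_per_kg: 10
  unconjugated_plasma_AUC: 5.6
study:
  dose_mg_per_kg: [10]
  route: bolus
  infusion_duration_h: 0
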