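species,dose_mg_per_kg,total_AUC_ug_ml_h,total_half_life_h,total_plasma_CL_L_h_kg,released_AUC_ug_ml_h,released_half_life_h,released_plasma_CL_L_h_kg
mouse,10,2294,7.4,0.004,38.7,7.6,0.26
rat,55,19593,6.8,0.003,373,11.5,0.15
rat,110,40187,8,0.003,694,14,0.16
rat,505,136989,15,0.004,1714,20.7,0.3
dog,12,1812,7.8,0.007,56.3,7.9,0.21
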