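species,dose_mg_per_kg,administration,plasma_AUC_ug_ml_h,hep_Clint_ul_min_e6,pred_blood_CL_L_h_kg,pred_plasma_CL_L_h_kg,in_vivo_blood_CL_L_h_kg,in_vivo_plasma_CL_L_h_kg
mouse,10,bolus,5.6,36,2,1.7,2.3,2
rat,50,infusion_0.5h,28,48.7,2.8,2.4,2.1,1.8
dog,12,infusion_3h,8.9,98.3,2.5,2.4,1.5,1.5
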