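species,body_weight_kg,cardiac_output_ml_min_kg,qh_ml_min_kg,liver_g_per_kg,hematocrit,plasma_l_per_kg,venous_l_per_kg,arterial_l_per_kg,lung_l_per_kg,sitt_h,lumen_volume_l,intestine_radius_cm
mouse,0.02,400,90,87.5,0.45,0.0272,0.0325,0.0165,0.0073,1.5,0.0003,0.15
rat,0.25,300,55.2,40,0.45,0.0312,0.049,0.025,0.005,1.5,0.004,0.25
beagle,10,120,30.9,32.1,0.45,0.0515,0.055,0.027,0.008,2.0,0.035,1.0
monkey,4,150,43.6,30,0.45,0.0448,0.037,0.019,0.008,2.8,0.014,0.9
human,70,80,20.7,25.7,0.45,0.0436,0.0514,0.0257,0.0076,3.32,0.105,1.75
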