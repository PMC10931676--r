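species,tissue,volume_l_per_kg,flow_frac_co
mouse,adipose,0.07,0.05
mouse,brain,0.0165,0.033
mouse,gut,0.0422,NA
mouse,heart,0.005,0.066
mouse,kidney,0.0167,0.091
mouse,liver,0.0875,NA
mouse,muscle,0.384,0.159
mouse,skin,0.1654,0.058
mouse,spleen,0.0035,NA
mouse,repro,0.0075,0.005
mouse,rest,0.09,NA
rat,adipose,0.07,0.07
rat,brain,0.0057,0.02
rat,gut,0.027,NA
rat,heart,0.0033,0.049
rat,kidney,0.0073,0.141
rat,liver,0.04,NA
rat,muscle,0.404,0.278
rat,skin,0.19,0.058
rat,spleen,0.002,NA
rat,repro,0.0095,0.005
rat,rest,0.09,NA
beagle,adipose,0.15,0.05
beagle,brain,0.008,0.02
beagle,gut,0.037,NA
beagle,heart,0.008,0.046
beagle,kidney,0.005,0.173
beagle,liver,0.0321,NA
beagle,muscle,0.457,0.217
beagle,skin,0.09,0.06
beagle,spleen,0.0026,NA
beagle,repro,0.001,0.001
beagle,rest,0.06,NA
monkey,adipose,0.07,0.04
monkey,brain,0.02,0.06
monkey,gut,0.03,NA
monkey,heart,0.005,0.045
monkey,kidney,0.005,0.15
monkey,liver,0.03,NA
monkey,muscle,0.43,0.15
monkey,skin,0.07,0.06
monkey,spleen,0.0025,NA
monkey,repro,0.001,0.001
monkey,rest,0.13,NA
human,adipose,0.2,0.05
human,brain,0.02,0.114
human,gut,0.0171,NA
human,heart,0.0047,0.04
human,kidney,0.0044,0.19
human,liver,0.0257,NA
human,muscle,0.4,0.17
human,skin,0.0371,0.058
human,spleen,0.0026,NA
human,repro,0.0005,0.0005
human,rest,0.15,NA
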