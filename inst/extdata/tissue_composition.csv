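tissue,f_ew,f_iw,f_nl,f_np,albumin_ratio,lipoprotein_ratio
adipose,0.135,0.017,0.79,0.002,0.049,0.068
brain,0.162,0.620,0.051,0.0565,0.048,0.041
gut,0.282,0.475,0.0487,0.0163,0.158,0.0141
heart,0.320,0.456,0.0115,0.0166,0.157,0.0160
kidney,0.273,0.483,0.0207,0.0162,0.130,0.137
liver,0.161,0.573,0.0348,0.0252,0.086,0.161
lung,0.336,0.446,0.0219,0.0140,0.212,0.168
muscle,0.118,0.630,0.0100,0.0072,0.064,0.059
skin,0.382,0.291,0.0284,0.0111,0.277,0.096
spleen,0.207,0.579,0.0201,0.0198,0.097,0.207
repro,0.255,0.525,0.0175,0.0092,0.075,0.075
rest,0.300,0.450,0.0400,0.0100,0.100,0.100
plasma,0.945,0.000,0.0023,0.0013,1,1
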