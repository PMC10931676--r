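compound,papp_ab_1e6_cm_s,papp_ba_1e6_cm_s,efflux_ratio_reported
Atenolol,0.73,NA,NA
Propranolol,29.38,NA,NA
Digoxin,0.65,14.64,22.48
E0703,1.68,3.74,2.22
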