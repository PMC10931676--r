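isoform,rate,abundance,normalized_rate_reported
CYP1A2,0.58,45,25.95
CYP2C9,0.06,96,5.33
CYP2C19,0.09,19,1.71
CYP2A6,0.06,68,4.08
CYP2D6,0.83,10,8.3
CYP3A4,1.5,108,162.33
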