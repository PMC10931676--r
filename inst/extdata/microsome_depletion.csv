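species,t_half_min,qh_ml_min_kg
beagle,157.5,30.9
mouse,69.3,90
monkey,83.5,43.6
human,105,20.7
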