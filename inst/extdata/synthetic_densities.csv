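eccentricity_deg,rgc_rf_density_per_deg2,cone_density_per_deg2
1.4142,450,3207
5.6569,121,920
9.8995,64,586
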