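stratum,weight
age_0_24,0.3533
age_25_44,0.2983
age_45_64,0.2146
age_65_plus,0.1338
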