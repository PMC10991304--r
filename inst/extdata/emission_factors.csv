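pollutant,ef_g_per_kg,cv
PM2.5,7.6,0.1
SO2,0.85,0.1
NOx,3.3,0.1
NH3,0.37,0.1
CH4,3.4,0.1
CO2,1460,0.1
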