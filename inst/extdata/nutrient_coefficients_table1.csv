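region,nutrient,fraction,cv
NC,n,0.0049,0.1
NC,p,0.00032,0.1
NC,k,0.01801,0.1
CC,n,0.0052,0.1
CC,p,0.00037,0.1
CC,k,0.01809,0.1
SC,n,0.0051,0.1
SC,p,0.00032,0.1
SC,k,0.01801,0.1
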