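landform,buffer_lo_m,buffer_hi_m,restorable_area_ha,successful_area_ha,attempted_area_ha
channel,0,3,207.2,61.88,100
floodplain,3,12,765.61,76.07,100
upper_bank,12,24,1334.75,26.78,100
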