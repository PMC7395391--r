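landform,age,abg_c
channel,0,0
channel,5,134.65
channel,10,150.65
channel,15,152.55
channel,20,152.78
channel,25,152.81
channel,30,152.81
channel,35,152.81
channel,40,152.81
channel,45,152.81
channel,50,152.81
floodplain,0,0
floodplain,5,171.52
floodplain,10,214.86
floodplain,15,225.82
floodplain,20,228.58
floodplain,25,229.28
floodplain,30,229.46
floodplain,35,229.50
floodplain,40,229.52
floodplain,45,229.52
floodplain,50,229.52
upper_bank,0,0
upper_bank,5,153.41
upper_bank,10,186.43
upper_bank,15,193.54
upper_bank,20,195.07
upper_bank,25,195.40
upper_bank,30,195.47
upper_bank,35,195.49
upper_bank,40,195.49
upper_bank,45,195.49
upper_bank,50,195.49
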