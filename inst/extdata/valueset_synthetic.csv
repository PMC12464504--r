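dimension,level,decrement
MO,1,0
MO,2,0.042
MO,3,0.0875
MO,4,0.1925
MO,5,0.35
SC,1,0
SC,2,0.036
SC,3,0.075
SC,4,0.165
SC,5,0.3
UA,1,0
UA,2,0.03
UA,3,0.0625
UA,4,0.1375
UA,5,0.25
PD,1,0
PD,2,0.0336
PD,3,0.07
PD,4,0.154
PD,5,0.28
AD,1,0
AD,2,0.02532
AD,3,0.05275
AD,4,0.11605
AD,5,0.211
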