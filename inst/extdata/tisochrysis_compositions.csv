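species_id,C,N
CO2,1,0
H2O,0,0
Pi,0,0
GAP,3,0
O2,0,0
G6P,6,0
H,0,0
PEP,3,0
CARB,6,0
NO3,0,1
SO4,0,0
Mg,0,0
PA,,
B,,
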