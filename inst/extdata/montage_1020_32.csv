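channel,theta_deg,phi_deg
Fp1,72,-18
Fp2,72,18
F7,72,-54
F3,51.007,-33.859
Fz,36,0
F4,51.007,33.859
F8,72,54
FC5,52.704,-67.614
FC1,27.192,-45
FC2,27.192,45
FC6,52.704,67.614
T7,72,-90
C3,36,-90
Cz,0,0
C4,36,90
T8,72,90
TP9,98,-108
CP5,52.704,-112.386
CP1,27.192,-135
CP2,27.192,135
CP6,52.704,112.386
TP10,98,108
P7,72,-126
P3,51.007,-146.141
Pz,36,180
P4,51.007,146.141
P8,72,126
PO9,98,-144
O1,72,-162
Oz,72,180
O2,72,162
PO10,98,144
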