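channel,x,y
Fp1,-0.31,0.95
Fp2,0.31,0.95
Fz,0.00,0.40
F3,-0.55,0.49
F4,0.55,0.49
F7,-0.80,0.58
F8,0.80,0.58
FC1,-0.33,0.21
FC2,0.33,0.21
FC5,-0.77,0.30
FC6,0.77,0.30
Cz,0.00,0.00
C3,-0.50,0.00
C4,0.50,0.00
T3,-1.00,0.00
T4,1.00,0.00
CP1,-0.33,-0.21
CP2,0.33,-0.21
CP5,-0.77,-0.30
CP6,0.77,-0.30
Pz,0.00,-0.40
P3,-0.55,-0.49
P4,0.55,-0.49
P7,-0.80,-0.58
P8,0.80,-0.58
PO3,-0.36,-0.73
PO4,0.36,-0.73
PO7,-0.58,-0.80
PO8,0.58,-0.80
Oz,0.00,-1.00
O1,-0.31,-0.95
O2,0.31,-0.95
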