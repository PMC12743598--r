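symbol,Z,A,I_eV
H,1,1.008,19.2
C,6,12.01,78.0
N,7,14.01,82.0
O,8,16.00,95.0
Na,11,22.99,149.0
Mg,12,24.31,156.0
P,15,30.97,173.0
S,16,32.06,180.0
Cl,17,35.45,174.0
K,19,39.10,190.0
Ca,20,40.08,191.0
Fe,26,55.85,286.0
I,53,126.9,491.0
Ar,18,39.95,188.0
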