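solution,rotation_90,couch_edge
1,-0.12,1.18
2,0.35,1.33
3,-1.00,1.13
4,0.64,-1.20
5,-0.13,1.25
6,-0.95,1.15
7,0.32,-1.27
8,0.47,-1.24
9,0.97,1.09
10,-1.10,1.50
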