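solution,h_ratio,w_h2o,w_d2o,snr_fse,snr_gre
1,1.00,100.00,0.00,130.78,30.43
2,0.95,95.09,4.97,124.98,31.79
3,0.90,89.94,10.06,118.14,27.23
4,0.85,84.98,15.02,110.93,21.53
5,0.80,79.99,20.01,104.49,24.58
6,0.70,70.17,29.83,92.48,20.65
7,0.60,60.00,40.00,79.11,18.65
8,0.50,50.08,49.92,64.95,14.15
9,0.40,39.78,60.22,51.53,10.36
10,0.30,29.95,70.05,39.27,6.53
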