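label,kind,soft,bone,lung,dof_lung
Linear regression fit,A,2.51,0.94,0.05,5
Variability in tissue composition,B,4.60,1.73,0.66,10
Sensitivity to proton energy variation,,0.05,0.14,0.00,
Positional uncertainty in FSE,A,2.94,1.39,1.00,19
Voxel-level uncertainty in SNR,A,3.38,1.77,1.50,149
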