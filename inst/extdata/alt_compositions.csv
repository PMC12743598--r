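name,group,source,note,rho_g_cm3,lipid_pct,H,C,N,O,Na,Mg,P,S,Cl,K,Ca,Fe,I,Ar
Adipose grade 1,soft,WW1986,transcribed,0.97,59.56,11.2,51.7,1.3,35.5,0.1,0,0,0.1,0.1,0,0,0,0,0
Adipose grade 2,soft,WW1986,transcribed,0.95,70.38,11.4,59.8,0.7,27.8,0.1,0,0,0.1,0.1,0,0,0,0,0
Adipose grade 3,soft,WW1986,transcribed,0.93,81.19,11.6,68.1,0.2,19.8,0.1,0,0,0.1,0.1,0,0,0,0,0
Mammary gland grade 1,soft,WW1986,reconstructed,0.99,,10.9,50.6,2.3,35.8,0.1,0,0.1,0.1,0.1,0,0,0,0,0
Mammary gland grade 3,soft,WW1986,reconstructed,1.06,,10.2,18.4,3.2,67.7,0.1,0,0.1,0.2,0.1,0,0,0,0,0
Liver grade 1,soft,WW1986,reconstructed,1.05,,10.3,15.6,2.7,70.1,0.2,0,0.3,0.3,0.2,0.3,0,0,0,0
Liver grade 3,soft,WW1986,reconstructed,1.07,,10.1,12.6,3.3,72.6,0.2,0,0.3,0.3,0.2,0.4,0,0,0,0
Muscle grade 1,soft,WW1986,reconstructed,1.05,,10.1,17.1,3.6,68.1,0.1,0,0.2,0.3,0.1,0.4,0,0,0,0
Muscle grade 3,soft,WW1986,reconstructed,1.04,,10.2,11.2,3.0,74.5,0.1,0,0.2,0.3,0.1,0.4,0,0,0,0
Adipose,soft,ICRP110,transcribed,0.95,,11.4,58.8,0.8,28.7,0.1,0,0,0.1,0.1,0,0,0,0,0
Muscle,soft,ICRP110,transcribed,1.05,,10.2,14.2,3.4,71.1,0.1,0,0.2,0.3,0.1,0.4,0,0,0,0
Prostate,soft,ICRP110,reconstructed,1.04,,10.5,8.9,2.5,77.4,0.2,0,0.1,0.2,0.2,0,0,0,0,0
Pancreas,soft,ICRP110,reconstructed,1.05,,10.6,15.7,2.4,70.4,0.2,0,0.2,0.1,0.2,0.2,0,0,0,0
Air,lung_related,ICRP110,transcribed,0.001,,0,0,75.5,23.2,0,0,0,0,0,0,0,0,0,1.3
Lung (compressed),lung_related,ICRP110,transcribed,0.382,,10.3,10.7,3.2,74.6,0.2,0,0.2,0.3,0.3,0.2,0,0,0,0
Cortical bone,bone,ICRP110,transcribed,1.92,,3.6,15.9,4.2,44.8,0.3,0.2,9.4,0.3,0,0,21.3,0,0,0
Cortical bone,bone,Hough2011,transcribed,1.92,,3.5,16.0,4.2,44.5,0.1,0.2,9.5,0.3,0,0,21.7,0,0,0
Spongiosa (femur),bone,Hough2011,reconstructed,1.12,,9.2,42.0,2.5,38.3,0.1,0.1,2.4,0.2,0.2,0.1,4.8,0.1,0,0
Spongiosa (vertebra),bone,Hough2011,reconstructed,1.24,,8.0,38.0,3.0,36.5,0.1,0.1,4.3,0.2,0.2,0.1,9.4,0.1,0,0
Spongiosa (rib),bone,Hough2011,reconstructed,1.32,,7.2,32.0,3.5,40.0,0.1,0.1,5.3,0.2,0.2,0.1,11.2,0.1,0,0
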