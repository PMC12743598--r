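name,group,source,rho_g_cm3,H,C,N,O,Na,Mg,P,S,Cl,K,Ca,Fe,I
Adipose,soft,ICRU46,0.95,11.4,59.8,0.7,27.8,0.1,0,0,0.1,0.1,0,0,0,0
Blood (whole),soft,ICRU46,1.06,10.2,11.0,3.3,74.5,0.1,0,0.1,0.2,0.3,0.2,0,0.1,0
Brain (whole),soft,ICRU46,1.04,10.7,14.5,2.2,71.2,0.2,0,0.4,0.2,0.3,0.3,0,0,0
GI tract,soft,ICRU46,1.03,10.6,11.5,2.2,75.1,0.1,0,0.1,0.1,0.2,0.1,0,0,0
Heart (empty),soft,ICRU46,1.05,10.4,13.9,2.9,71.8,0.1,0,0.2,0.2,0.2,0.3,0,0,0
Heart (blood filled),soft,ICRU46,1.06,10.3,12.1,3.2,73.4,0.1,0,0.1,0.2,0.3,0.2,0,0.1,0
Kidney,soft,ICRU46,1.05,10.3,13.2,3.0,72.4,0.2,0,0.2,0.2,0.2,0.2,0.1,0,0
Liver,soft,ICRU46,1.06,10.2,13.9,3.0,71.6,0.2,0,0.3,0.3,0.2,0.3,0,0,0
Lung (inflated),lung_related,ICRU46,0.26,10.3,10.5,3.1,74.9,0.2,0,0.2,0.3,0.3,0.2,0,0,0
Lung (congested),soft,ICRU46,1.04,10.5,10.7,3.2,74.4,0.2,0,0.2,0.3,0.3,0.2,0,0,0
Muscle,soft,ICRU46,1.05,10.2,14.3,3.4,71.0,0.1,0,0.2,0.3,0.1,0.4,0,0,0
Pancreas,soft,ICRU46,1.04,10.6,16.9,2.2,69.4,0.2,0,0.2,0.1,0.2,0.2,0,0,0
Spleen,soft,ICRU46,1.06,10.3,11.3,3.2,74.1,0.1,0,0.3,0.2,0.2,0.3,0,0,0
Skin,soft,ICRU46,1.09,10.0,20.4,4.2,64.5,0.2,0,0.1,0.2,0.3,0.1,0,0,0
Mammary gland,soft,ICRU46,1.02,10.6,33.2,3.0,52.7,0.1,0,0.1,0.2,0.1,0,0,0,0
Thyroid,soft,ICRU46,1.05,10.4,11.9,2.4,74.5,0.2,0,0.1,0.1,0.2,0.1,0,0,0.1
Testis,soft,ICRU46,1.04,10.6,9.9,2.0,76.6,0.2,0,0.1,0.2,0.2,0.2,0,0,0
Ovary,soft,ICRU46,1.05,10.5,9.3,2.4,76.8,0.2,0,0.2,0.2,0.2,0.2,0,0,0
Urinary bladder (empty),soft,ICRU46,1.04,10.5,9.6,2.6,76.1,0.2,0,0.2,0.2,0.3,0.3,0,0,0
Urinary bladder (filled),soft,ICRU46,1.03,10.8,3.5,1.5,83.0,0.3,0,0.1,0.1,0.5,0.2,0,0,0
Ribs (whole) 2nd 6th,bone,ICRU46,1.41,6.4,26.3,3.9,43.6,0.1,0.1,6.0,0.3,0.1,0.1,13.1,0,0
Ribs (whole) 10th,bone,ICRU46,1.52,5.6,23.5,4.0,43.4,0.1,0.1,7.2,0.3,0.1,0.1,15.6,0,0
Spongiosa,bone,ICRU46,1.18,8.5,40.4,2.8,36.7,0.1,0.1,3.4,0.2,0.2,0.1,7.4,0.1,0
Cartilage,bone,ICRU46,1.10,9.6,9.9,2.2,74.4,0.5,0,2.2,0.9,0.3,0,0,0,0
Cranium (whole),bone,ICRU46,1.61,5.0,21.2,4.0,43.5,0.1,0.2,8.1,0.3,0,0,17.6,0,0
Femur (whole) 30yr,bone,ICRU46,1.33,7.0,34.5,2.8,36.8,0.1,0.1,5.5,0.2,0.1,0.1,12.8,0,0
Humerus (whole),bone,ICRU46,1.46,6.0,31.4,3.1,36.9,0.1,0.1,7.0,0.2,0.1,0.1,15.0,0,0
Mandible (whole),bone,ICRU46,1.68,4.6,19.9,4.1,43.5,0.1,0.2,8.6,0.3,0,0,18.7,0,0
Sacrum (whole) Male,bone,ICRU46,1.29,7.4,30.2,3.7,43.8,0.1,0.1,4.5,0.2,0.1,0.1,9.8,0,0
Sacrum (whole) Female,bone,ICRU46,1.39,6.6,27.1,3.8,43.7,0.1,0.1,5.7,0.2,0.1,0.1,12.5,0,0
Vertebra (whole) C4,bone,ICRU46,1.42,6.3,26.1,3.9,43.6,0.1,0.1,6.1,0.3,0.1,0.1,13.3,0,0
Vertebra (whole) D6 L3,bone,ICRU46,1.33,7.0,28.7,3.8,43.7,0.1,0.1,5.1,0.2,0.1,0.1,11.1,0,0
Cortical bone,bone,ICRU46,1.92,3.4,15.5,4.2,43.5,0.1,0.2,10.3,0.3,0,0,22.5,0,0
Water,reference,ICRU46,1.00,11.2,0,0,88.8,0,0,0,0,0,0,0,0,0
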