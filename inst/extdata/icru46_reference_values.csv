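name,group,h_ratio,spr
Adipose,soft,0.967,0.970
Blood (whole),soft,0.965,1.051
Brain (whole),soft,0.994,1.037
GI tract,soft,0.975,1.027
Heart (empty),soft,0.975,1.044
Heart (blood filled),soft,0.975,1.053
Kidney,soft,0.966,1.043
Liver,soft,0.965,1.051
Lung (inflated),lung_related,0.239,0.258
Lung (congested),soft,0.975,1.034
Muscle,soft,0.956,1.041
Pancreas,soft,0.984,1.039
Spleen,soft,0.975,1.053
Skin,soft,0.973,1.081
Mammary gland,soft,0.965,1.024
Thyroid,soft,0.975,1.044
Testis,soft,0.984,1.036
Ovary,soft,0.984,1.044
Urinary bladder (empty),soft,0.975,1.034
Urinary bladder (filled),soft,0.993,1.026
Ribs (whole) 2nd 6th,bone,0.806,1.315
Ribs (whole) 10th,bone,0.760,1.397
Spongiosa,bone,0.896,1.144
Cartilage,bone,0.943,1.079
Cranium (whole),bone,0.719,1.462
Femur (whole) 30yr,bone,0.831,1.255
Humerus (whole),bone,0.782,1.352
Mandible (whole),bone,0.690,1.514
Sacrum (whole) Male,bone,0.852,1.226
Sacrum (whole) Female,bone,0.819,1.300
Vertebra (whole) C4,bone,0.799,1.322
Vertebra (whole) D6 L3,bone,0.831,1.255
Cortical bone,bone,0.583,1.691
Water,soft,1.000,1.000
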