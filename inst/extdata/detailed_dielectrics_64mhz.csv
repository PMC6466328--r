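tissue,label,sigma_S_per_m,eps_r,rho_kg_per_m3
Background,0,0,1,0
Skin,1,0.44,92.2,1109
Fat,2,0.07,13.6,911
Muscle,3,0.69,72.2,1090
Cortical_bone,4,0.06,16.7,1908
Spongy_bone,5,0.16,30.9,1178
Lung,6,0.29,37.1,394
Heart,7,0.68,106.5,1081
Liver,8,0.45,80.6,1079
Stomach,9,0.88,85.8,1088
Kidney,10,0.74,118.6,1066
Spleen,11,0.74,110.6,1089
Intestine,12,0.68,94.7,1088
Grey_matter,13,0.51,97.4,1045
White_matter,14,0.29,67.8,1041
Cerebellum,15,0.72,116.3,1045
Skull,16,0.13,26.4,1908
Eyes,17,1.50,69.1,1005
Cartilage,18,0.60,66.8,1100
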