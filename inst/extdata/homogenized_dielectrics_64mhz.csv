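tissue,label,sigma_S_per_m,eps_r,rho_kg_per_m3
Background,0,0,1,0
Eyes,1,1.24,70.96,1005
Brain,2,0.69,72.35,1045
Cartilage,3,0.60,66.76,1100
Skull,4,0.13,26.38,1908
Muscle,5,0.69,72.24,1090
Stomach,6,0.88,85.81,1088
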