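individual,region,level,r_spearman,R2,p,n,length_mm
A,T,T11,0.721,0.521,0.001,295,36.2
A,T,T12,0.687,0.291,0.001,300,29.3
A,L,L1,0.107,0.02,0.051,330,32.6
A,L,L2,0.524,0.227,0.001,429,46.0
A,L,L3,0.512,0.350,0.001,436,43.0
A,L,L4,0.469,0.281,0.001,414,40.1
A,L,L5,0.542,0.343,0.001,416,40.5
B,T,T12,0.686,0.290,0.001,309,29.9
B,L,L1,0.400,0.140,0.001,418,41.7
B,L,L2,0.204,0.029,0.001,287,30.9
B,L,L3,0.202,0.042,0.001,398,39.1
B,L,L4,0.659,0.520,0.001,385,38.3
B,L,L5,0.690,0.137,0.001,401,39.1
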