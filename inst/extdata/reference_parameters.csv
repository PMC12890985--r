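protein,U0,c,d,n
lambda-repressor,2.1,12,2.7,3
alpha3D,3.2,21,5.3,3
protein-G,5.0,14,5.1,3
Ala9,1.3,9,4.0,5
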