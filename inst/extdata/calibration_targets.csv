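marker,condition,value,tolerance,weight
ros,stressed,171.92,0.02,1
cortisol,stressed,106.7,0.02,1
tnfa,stressed,2.2e-3,0.02,1
ros,combined,5.58,0.02,1
cortisol,combined,8.57,0.02,1
tnfa,combined,4.1e-5,0.02,1
aldosterone,combined,0.9996,0.02,1
tnfa,single:vitamin_a,25,0.08,0.5
tnfa,single:gotukola,11,0.18,0.5
ros,single:gotukola,24,0.09,0.5
ros,single:acerola,21,0.10,0.5
ros,single:zinc,11,0.18,0.5
ros,single:vitamin_c,11,0.18,0.5
cortisol,single:acerola,22,0.09,0.5
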