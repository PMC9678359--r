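patient,mean_hand,mean_face,sd_hand,sd_face
A,2.75,1.98,0.75,0.97
B,3.17,2.07,0.69,1.06
C,3.57,1.43,0.50,0.50
D,2.80,1.88,0.80,0.76
E,2.27,2.27,1.01,1.12
F,2.20,1.97,0.94,0.92
G,2.12,2.08,1.06,1.01
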