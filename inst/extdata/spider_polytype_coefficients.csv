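predator,prey_stage,a,b,c,d,r_squared
E. tricuspidata,nymph_4_5,0.961,-0.008,0.0006,-8.642e-7,0.733
X. ephippiatus,nymph_4_5,1.321,-0.029,0.002,-3.901e-5,0.774
H. graminicola,nymph_4_5,0.884,-0.019,0.0002,-3.211e-6,0.727
O. sertatus,nymph_4_5,1.018,-0.012,0.001,-9.631e-6,0.853
E. tricuspidata,adult,1.021,-0.021,0.001,-2.778e-5,0.647
X. ephippiatus,adult,1.056,-0.027,0.0005,-8.642e-6,0.821
H. graminicola,adult,1.292,-0.105,0.005,-8.877e-5,0.831
O. sertatus,adult,0.991,-0.016,0.001,-1.272e-5,0.661
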