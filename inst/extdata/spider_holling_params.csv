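predator,prey_stage,model,attack_rate,handling_time,exposure_T,r_squared
E. tricuspidata,nymph_4_5,II,1.276,0.023,1,0.975
X. ephippiatus,nymph_4_5,II,1.256,0.037,1,0.961
H. graminicola,nymph_4_5,II,1.067,0.045,1,0.955
O. sertatus,nymph_4_5,II,1.339,0.022,1,0.976
E. tricuspidata,adult,II,1.231,0.025,1,0.969
X. ephippiatus,adult,II,1.290,0.041,1,0.962
H. graminicola,adult,II,1.085,0.049,1,0.951
O. sertatus,adult,II,1.206,0.024,1,0.968
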