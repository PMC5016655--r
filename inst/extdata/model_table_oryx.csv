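id,density_model,k,aicc,delta_aicc,weight
1,rock_cover + richness,5,524.718,0.000,0.488
2,rock_cover + habitat,5,525.626,0.901,0.310
3,rock_cover + herb_height,5,528.079,3.362,0.091
4,rock_cover + herb_cover,5,528.752,4.034,0.065
5,null,3,555.984,31.267,0.000
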