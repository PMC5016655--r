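id,density_model,k,aicc,delta_aicc,weight
1,rock_cover + richness,5,670.333,0.000,0.571
2,rock_cover + habitat,5,672.842,2.509,0.163
3,rock_cover + species,5,672.844,2.511,0.163
4,rock_cover + herb_height,5,675.356,5.023,0.046
5,rock_cover + herb_cover,5,675.671,5.338,0.040
6,null,3,710.192,39.858,0.000
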