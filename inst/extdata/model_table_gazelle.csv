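id,density_model,k,aicc,delta_aicc,weight
1,herb_height * litter_cover,6,318.246,0.000,0.184
2,herb_height,4,318.781,0.535,0.141
3,litter_cover,4,319.157,0.911,0.117
4,herb_cover,4,319.265,1.019,0.111
5,nonwoody_biomass,4,320.477,2.231,0.060
6,null,3,320.800,2.554,0.051
7,water_content,4,320.933,2.687,0.048
8,east_west,4,321.591,3.345,0.035
9,tree_cover,4,321.782,3.536,0.031
10,habitat,4,321.890,3.644,0.030
11,north_south,4,321.905,3.659,0.030
12,tree_height,4,322.089,3.843,0.027
13,shrub_cover,4,322.140,3.894,0.026
14,shrub_height,4,322.183,3.937,0.026
15,richness,4,322.402,4.156,0.023
16,woody_biomass,4,322.670,4.424,0.020
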