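variable,description,M_crassipes,L_coco,M_insignis
Ele,Elevation,3.8,14,6.1
bio2,Mean Diurnal Range,5.5,23.4,1.1
bio4,Temperature Seasonality,0.1,11.3,42.1
bio9,Mean Temperature in the Driest Quarter,3.7,34.8,30.5
bio12,Annual Precipitation,3.7,0.1,1.7
bio14,Precipitation in the Driest Month,1.8,0.4,0.6
bio17,Precipitation in the Driest Quarter,70.8,0,3.2
bio19,Precipitation in the Coldest Quarter,0.7,1.2,0.7
T_BS,Topsoil Base Saturation,3.6,0,0
S_BS,Subsoil Base Saturation,0.7,0,0.2
S_CACO3,Subsoil Calcium Carbonate,0,0,0.5
S_PH_H2O,Subsoil pH,0,0,0.7
S_SILT,Subsoil Silt Fraction,0,0.7,2.5
S_USDA_TEX,Subsoil USDA Texture Classification,0.2,6.4,1.3
UVB2,UV-B Seasonality,3.6,4.8,3.4
UVB3,Mean UV-B of the Highest Month,0,0,0
UVB4,Mean UV-B of the Lowest Month,0.2,0.7,4.6
UVB6,Sum of Monthly Mean UV-B during Lowest Quarter,1.5,2.2,0.6
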