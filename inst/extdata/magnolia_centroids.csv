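species,scenario,period,lon,lat,dist_printed
M_crassipes,current,current,115.26,27.46,NA
M_crassipes,SSP126,2050,114.23,27.40,103.66
M_crassipes,SSP126,2070,115.08,27.53,86.66
M_crassipes,SSP126,2090,114.99,26.96,64.70
M_crassipes,SSP245,2050,114.62,27.76,72.55
M_crassipes,SSP245,2070,115.03,27.13,81.73
M_crassipes,SSP245,2090,113.63,26.47,159.39
M_crassipes,SSP585,2050,114.62,27.13,73.79
M_crassipes,SSP585,2070,115.19,27.17,57.05
M_crassipes,SSP585,2090,113.69,26.47,170.51
L_coco,current,current,110.52,26.61,NA
L_coco,SSP126,2050,110.63,26.45,21.00
L_coco,SSP126,2070,110.46,26.39,17.92
L_coco,SSP126,2090,110.74,26.66,41.30
L_coco,SSP245,2050,110.82,26.84,40.58
L_coco,SSP245,2070,110.50,26.66,38.86
L_coco,SSP245,2090,110.79,26.76,31.53
L_coco,SSP585,2050,110.69,26.52,19.57
L_coco,SSP585,2070,110.29,26.26,50.44
L_coco,SSP585,2090,110.39,26.14,17.33
M_insignis,current,current,109.10,27.28,NA
M_insignis,SSP126,2050,108.59,27.35,51.85
M_insignis,SSP126,2070,108.87,27.31,28.65
M_insignis,SSP126,2090,108.91,27.38,9.09
M_insignis,SSP245,2050,108.81,27.47,35.69
M_insignis,SSP245,2070,108.30,27.28,55.57
M_insignis,SSP245,2090,108.68,27.56,49.53
M_insignis,SSP585,2050,108.95,27.24,15.90
M_insignis,SSP585,2070,107.73,27.11,124.00
M_insignis,SSP585,2090,107.34,26.82,50.82
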