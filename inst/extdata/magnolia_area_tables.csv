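species,scenario,period,minimal,moderate,high,total_suitable,change_printed,rate_printed
M_crassipes,current,current,NA,NA,14.57,83.96,NA,NA
M_crassipes,SSP126,2050,32.85,10.6,2.58,46.03,-37.93,-45.18
M_crassipes,SSP126,2070,42.45,20.54,9.15,72.14,26.11,56.72
M_crassipes,SSP126,2090,41.6,8.94,1.3,51.84,-20.31,-28.15
M_crassipes,SSP245,2050,32.21,9.00,0.85,42.05,-41.91,-49.92
M_crassipes,SSP245,2070,29.78,6.63,1.57,37.98,-4.07,-9.68
M_crassipes,SSP245,2090,11.72,1.38,0.02,13.12,-24.86,-65.46
M_crassipes,SSP585,2050,33.27,13.87,3.87,51.01,-32.95,-39.24
M_crassipes,SSP585,2070,20.55,10.06,5.46,36.07,-14.94,-29.29
M_crassipes,SSP585,2090,15.76,4.72,0.86,21.34,-14.73,-40.84
L_coco,current,current,NA,NA,18.33,116.22,NA,NA
L_coco,SSP126,2050,60.61,25.01,17.88,103.49,-12.73,-10.96
L_coco,SSP126,2070,56.35,24.39,17.93,98.67,-4.82,-4.66
L_coco,SSP126,2090,71.23,27.71,20.92,119.86,21.19,21.48
L_coco,SSP245,2050,76.73,28.89,19.91,125.54,9.32,7.77
L_coco,SSP245,2070,65.87,24.54,16.52,106.93,-18.61,-14.82
L_coco,SSP245,2090,68.5,25.74,17.64,111.87,4.94,4.62
L_coco,SSP585,2050,65.9,25.43,18.05,109.39,-6.83,-6.11
L_coco,SSP585,2070,56.56,23.78,16.14,96.48,-12.91,-11.80
L_coco,SSP585,2090,49.64,22.43,14.24,86.31,-10.17,-10.54
M_insignis,current,current,NA,NA,31.87,205.04,NA,NA
M_insignis,SSP126,2050,96.33,62.38,27.21,185.92,-19.11,-9.32
M_insignis,SSP126,2070,104.64,62.95,23.89,191.48,5.56,2.99
M_insignis,SSP126,2090,104.67,71.79,26.13,202.58,11.10,5.80
M_insignis,SSP245,2050,102.98,80.90,23.43,207.31,2.28,1.11
M_insignis,SSP245,2070,116.68,52.92,18.62,188.85,-18.46,-8.90
M_insignis,SSP245,2090,115.03,55.81,19.01,189.85,1.00,0.53
M_insignis,SSP585,2050,99.41,66.61,20.94,186.95,-18.08,-8.82
M_insignis,SSP585,2070,101.71,51.45,16.58,169.74,-17.21,-9.21
M_insignis,SSP585,2090,94.15,45.92,10.85,150.92,-18.82,-11.09
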