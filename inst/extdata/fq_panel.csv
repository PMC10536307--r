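compound,retention_time,linearity_low,linearity_high,r_squared,lod,loq,matrix_effect
marbofloxacin,7.21,0.1,200,0.994,0.17,0.54,104.6
fleroxacin,7.43,0.1,200,0.998,0.58,1.75,95.6
ofloxacin,7.88,0.1,200,0.999,0.15,0.54,99.4
pefloxacin,7.91,0.1,200,0.999,0.15,0.53,110.1
enoxacin,7.94,0.1,200,0.999,0.21,0.63,106.4
norfloxacin,8.18,0.1,200,0.999,0.35,1.0,103.8
ciprofloxacin,8.38,0.1,200,0.999,0.30,1.0,101.2
enrofloxacin,8.48,0.1,200,0.991,0.47,1.4,103.6
danofloxacin,8.49,0.1,200,0.996,0.28,0.85,92.9
lomefloxacin,8.64,0.1,200,0.999,1.03,3.10,106.4
difloxacin,8.74,0.1,200,0.992,0.16,0.68,96.4
sarafloxacin,8.89,0.1,200,0.998,0.2,0.59,104.7
flumequine,10.57,0.1,200,0.999,0.37,1.05,104.6
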