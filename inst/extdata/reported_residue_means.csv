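compound,stratum_type,stratum,mean_residue,sd_residue,max_residue
ciprofloxacin,overall,overall,1.06,10.88,NA
enrofloxacin,overall,overall,0.24,0.091,NA
norfloxacin,overall,overall,16.10,307.76,7890
ofloxacin,overall,overall,0.091,0.422,NA
ciprofloxacin,floral_origin,Chinese milk vetch,74.3,92.7,NA
norfloxacin,channel,bee product store,35.1,223.93,NA
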