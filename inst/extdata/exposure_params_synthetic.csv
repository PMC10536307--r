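age_group,intake_mean,intake_sd,bw_mean,bw_sd,n_surveyed
children 4-11,0.004,0.0025,25,6,320
adolescents 12-18,0.009,0.006,50,10,310
adults 19-64,0.015,0.010,62,10,980
older adults 65+,0.014,0.009,60,9,346
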