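compound,adi
ciprofloxacin,0.15
enrofloxacin,6.2
norfloxacin,14
ofloxacin,3.2
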