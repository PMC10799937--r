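level4,level3,level2,level1
fir_engraver,bark_beetles,insects,biotic
mtn_pine_beetle,bark_beetles,insects,biotic
western_pine_beetle,bark_beetles,insects,biotic
ips_engraver,bark_beetles,insects,biotic
defoliator_moth,defoliators,insects,biotic
root_disease,diseases,pathogens,biotic
canker,diseases,pathogens,biotic
drought,drought,abiotic_stress,abiotic
fire,fire,fire,abiotic
unknown,unknown,unknown,unknown
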