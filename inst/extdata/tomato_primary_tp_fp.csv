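class,tp,fp
leaf_mold,11022,900
gray_mold,1642,1126
canker,2226,422
plague,2246,324
miner,5198,85
low_temperature,426,51
powdery_mildew,314,24
whitefly,380,24
yellow_leaf_curl,3819,108
nutritional_excess,403,23
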