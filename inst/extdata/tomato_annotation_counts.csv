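class,images,boxes,printed_share
leaf_mold,1350,11922,24.06
gray_mold,335,2768,5.57
canker,309,2648,5.33
plague,296,2570,5.17
miner,339,5283,10.63
low_temperature,55,477,0.96
powdery_mildew,40,338,0.68
whitefly,49,404,0.81
nutritional_excess,50,426,0.85
yellow_leaf_curl,3927,3927,7.90
background,2177,18899,38.03
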