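class,ap_primary,ap_refined
leaf_mold,0.9060,0.9205
gray_mold,0.7968,0.8910
canker,0.8569,0.9376
plague,0.8762,0.9710
miner,0.8046,0.9947
low_temperature,0.7824,0.9821
powdery_mildew,0.6556,0.9963
whitefly,0.8301,0.9929
nutritional_excess,0.8971,0.9893
yellow_leaf_curl,0.8500,0.9500
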