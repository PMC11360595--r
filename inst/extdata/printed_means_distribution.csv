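site_id,medium,depth_top_cm,depth_bottom_cm,element,concentration,unit
MEAN,ice,0,5,Hg,7.90,ng/L
MEAN,ice,0,5,As,2.48,ug/L
MEAN,water,0,5,Hg,0.37,ug/L
MEAN,water,0,5,As,5.72,ug/L
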