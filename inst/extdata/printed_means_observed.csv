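site_id,medium,depth_top_cm,depth_bottom_cm,element,concentration,unit
MEAN,ice,0,5,Hg,8.20,ng/L
MEAN,ice,0,5,As,2.34,ug/L
MEAN,water,0,5,Hg,0.36,ug/L
MEAN,water,0,5,As,5.72,ug/L
MEAN,sediment,0,5,Hg,0.035,mg/kg
MEAN,sediment,0,5,As,7.47,mg/kg
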