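param,rel_lo,rel_hi
MAP_brachial_mid,0,25
MAP_aortic_root,-5,15
HR,10,45
SV,-50,-20
CO,-35,-5
CVP,-90,-40
TTI,-15,0
SW,-45,-20
PP_aortic_root,-40,-5
TPR,5,60
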