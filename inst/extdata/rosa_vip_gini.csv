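compound,vip,gini
(e)-2-hexenal,1.52633,0.69
ethyl caprylate,1.50715,0.65
beta-ocimene,1.22437,0.33
ethyl butanoate,1.12642,0.64
styrene,0.945676,0.25
(3z)-3-hexen-1-yl acetate,0.92031,0.08
methyl salicylate,0.908079,0.34
ethyl hexanoate,0.905574,0.08
nonanal,0.760134,0.19
alpha-ionone,0.628868,0.02
caryophyllene,0.502894,0.18
2-nonanol,0.137078,0.06
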