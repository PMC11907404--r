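element,unit,min_ng_g,max_ng_g
Cd,ng/g,8.8,115
As,ng/g,20,1148
Pb,ng/g,419,1884
Ni,ng/g,360,2470
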