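scenario,increased_area_mkm2,decreased_area_mkm2
F126,114.9,19.8
F585,110.6,23.0
M126,123.5,11.1
M585,120.9,13.8
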