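material,sigma_S_per_m,epsilon_r
Hydrogel,1/11,1
Skin,1/700,6000
Fat,1/33,25000
Muscle (axial),1/3,120000
Muscle (radial),1/9,40000
Bone,1/50,3000
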