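image,x1,y1,x2,y2,culture,genotype
control_c1_s1,900,1180,900,980,1,control
control_c1_s1,2140,2420,2300,2480,1,control
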