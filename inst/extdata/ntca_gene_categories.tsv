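category	n_genes
Cellular processes	234
Metabolism	151
Nitrogen metabolism and nitrogen fixation-related	121
Regulatory functions	179
Photosynthesis and respiration	57
Transport and binding proteins	124
Other categories	213
Hypothetical proteins	1074
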