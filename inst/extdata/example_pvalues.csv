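id,p
gene_1,0.0001
gene_2,0.0012
gene_3,0.016
gene_4,0.021
gene_5,0.048
gene_6,0.12
gene_7,0.33
gene_8,0.51
gene_9,0.74
gene_10,0.97
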