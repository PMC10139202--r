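class	n_positions	n_genes
up50k	8199	507
up10k	1893	120
up1k	236	9
intron	7232	744
exon	485	207
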