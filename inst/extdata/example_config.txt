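# synthetic genome configuration (key = value)
chrom_lengths = 300000,150000
n_genes       = 120
gene_len_mean = 2100
gene_len_sd   = 1600
genic_gc      = 0.393
intergenic_gc = 0.313
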