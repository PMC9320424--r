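term	set
intergenic_variant	a
upstream_gene_variant	a
downstream_gene_variant	a
5_prime_UTR_variant	a
3_prime_UTR_variant	a
intron_variant	b
regulatory_region_variant	c
TF_binding_site_variant	c
non_coding_transcript_variant	d
non_coding_transcript_exon_variant	d
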