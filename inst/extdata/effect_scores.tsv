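term	score
stop_gained	5
stop_lost	5
start_lost	5
frameshift_variant	5
splice_acceptor_variant	5
splice_donor_variant	5
missense_variant	4
inframe_insertion	4
inframe_deletion	4
splice_region_variant	4
synonymous_variant	3
stop_retained_variant	3
start_retained_variant	3
5_prime_UTR_variant	2
3_prime_UTR_variant	2
upstream_gene_variant	2
downstream_gene_variant	2
intron_variant	1
intergenic_variant	1
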