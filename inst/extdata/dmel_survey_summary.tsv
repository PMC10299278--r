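key	value
het_gene_hits	170
het_genes	80
nonhet_gene_hits	137
nonhet_genes	149
noncoding_insertions_total	162
noncoding_insertions_het	110
kp_canonical_length	2907
kp_reference_deletion_start	808
kp_reference_deletion_end	2560
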