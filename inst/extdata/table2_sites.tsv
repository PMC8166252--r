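gene	codon_index	codon_change	snp_id	ancestral_freq	ld_partners	archaic_state	ape_variation	decision
MAMLD1	726	AGT>AGA	NA	NA	NA	derived	none	TRUE_PSS
MAMLD1	728	GGC>GAC	NA	NA	NA	derived	none	TRUE_PSS
PRDM9	155	CCT>TCT	NA	NA	NA	derived	variable	TRUE_PSS
PRDM9	573	ACA>ATA	rs199686868	0.02	NA	derived	variable	TRUE_PSS
PRDM9	591	CGG|CAG|GTT>TGG	rs200381384	0.06	NA	derived	variable	TRUE_PSS
PRDM9	629	ACA>AGA	rs112192848	0.01	NA	derived	variable	TRUE_PSS
PRDM9	657	ACA>AGA	rs112679149	0.01	NA	derived	variable	TRUE_PSS
PRDM9	681	AGA|AGT>ACT	rs6875787	0.75	NA	missing	variable	MINOR_ALLELE
PRDM9	737	TGT|ATT>AGA	NA	NA	NA	derived	variable	TRUE_PSS
ZNF860	219	CAA>CTA	NA	NA	NA	derived	none	TRUE_PSS
ZNF860	348	GAC>GAA	rs13064905	0.80	464|609	heterozygous	missing	FALSE_POSITIVE
ZNF860	464	AGT|CGT>CAT	rs1808125	0.90	348|609	heterozygous	missing	FALSE_POSITIVE
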