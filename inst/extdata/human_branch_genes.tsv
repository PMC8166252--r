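gene	family	krab_znf	consensus_sites
MAMLD1	mastermind-like	FALSE	2
PRDM9	KRAB-ZNF	TRUE	7
ZNF626	KRAB-ZNF	TRUE	0
ZNF806	KRAB-ZNF	TRUE	0
ZNF860	KRAB-ZNF	TRUE	3
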