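tss_id	chrom	pos	source	ue	discordant
TSS:166149160	chr2	166149160	CAGE	h1a	FALSE
TSS:h1a-unplaced-1	chr2	NA	CAGE	h1a	FALSE
TSS:166128050	chr2	166128050	CAGE	h1a	TRUE
TSS:166128014	chr2	166128014	CAGE	h1b	FALSE
TSS:166127981	chr2	166127981	CAGE	h1b	FALSE
TSS:h1b-unplaced-1	chr2	NA	CAGE	h1b	FALSE
TSS:gene-body	chr2	NA	CAGE	gene-body	FALSE
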