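chr2	165995000	166149400	ENST00000641575	0	-	165995500	166073000	0	4	1500,3000,401,401	0,75000,82899,153999
chr2	165995000	166128150	ENST00000674923	0	-	165995500	166073000	0	4	1500,3000,401,201	0,75000,82899,132949
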