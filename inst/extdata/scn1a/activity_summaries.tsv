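tss	group	mean_tpm	se	n
TSS:166128014	brain	44.1533	NA	NA
TSS:166149160	brain	19.7896	NA	NA
TSS:gene-body	brain	0	NA	NA
TSS:166128014	astrocyte-cortex	7.3615	NA	3
TSS:166127981	astrocyte-cortex	1.5472	NA	3
TSS:166128050	astrocyte-cortex	0.0994	NA	3
TSS:166128014	neuron	4.1252	NA	3
TSS:166127981	neuron	0.8320	NA	3
TSS:166149160	astrocyte-cerebellum	0	0	3
TSS:h1a-unplaced-1	astrocyte-cerebellum	0	0	3
TSS:166128050	astrocyte-cerebellum	0	0	3
TSS:166128014	astrocyte-cerebellum	0	0	3
TSS:166127981	astrocyte-cerebellum	0	0	3
TSS:h1b-unplaced-1	astrocyte-cerebellum	0	0	3
TSS:gene-body	astrocyte-cerebellum	0	0	3
TSS:166149160	iPSC-neuron	0	0	24
TSS:h1a-unplaced-1	iPSC-neuron	0	0	24
TSS:166128050	iPSC-neuron	0	0	24
TSS:166128014	iPSC-neuron	0	0	24
TSS:166127981	iPSC-neuron	0	0	24
TSS:h1b-unplaced-1	iPSC-neuron	0	0	24
TSS:gene-body	iPSC-neuron	0	0	24
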