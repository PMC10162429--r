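name	chrom	start	end
h1a	chr2	166149000	166149400
h1b	chr2	166127950	166128150
h1c	chr2	166077900	166078300
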