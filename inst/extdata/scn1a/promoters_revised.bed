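chr2	166148179	166151550	P1a*
chr2	166127359	166129030	P1b*
chr2	166077139	166079490	P1c*
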