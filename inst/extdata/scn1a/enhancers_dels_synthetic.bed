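chr2	165741999	165750300	dELS_near
chr2	165279799	165282900	dELS_far
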