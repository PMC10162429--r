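chr2	165741899	165750100	CTS_near
chr2	165279899	165283100	CTS_far
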