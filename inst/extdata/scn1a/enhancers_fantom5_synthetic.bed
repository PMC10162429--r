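chr2	165741799	165750400	F5_near
chr2	165279499	165283000	F5_far
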