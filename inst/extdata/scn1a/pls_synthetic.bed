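chr2	166128299	166128700	PLS_h1b
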