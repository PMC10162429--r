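ue	kb	citation
h1a	2.5	Long2008
h1b	1.2	Nakayama2010
h1c	1.0	Dong2014
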