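chr2	165741999	165742600	GRN_near_1
chr2	165743199	165743800	GRN_near_2
chr2	165744499	165745000	GRN_near_3
chr2	165745599	165746300	GRN_near_4
chr2	165746999	165747500	GRN_near_5
chr2	165748199	165748900	GRN_near_6
chr2	165749499	165750200	GRN_near_7
chr2	165279999	165280800	GRN_far_1
chr2	165281999	165282700	GRN_far_2
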