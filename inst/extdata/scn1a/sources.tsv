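source	path	species
GRN	enhancers_grn_synthetic.bed	human
high-confidence	enhancers_hc_synthetic.bed	human
FANTOM5-enhancers	enhancers_fantom5_synthetic.bed	human
cCRE-dELS	enhancers_dels_synthetic.bed	human
cell-type-specific	enhancers_celltype_synthetic.bed	human
cross-species	enhancers_mouse_synthetic.bed	mouse-lifted
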