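subtype	n_cases	n_lmd
AITL	48	13
nodal_PTCL_TFH	5	1
PTCL_NOS_TFH	34	5
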