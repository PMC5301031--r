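gene	subtype	n_mutated	n_mutated_lmd
TET2	AITL	36	12
TET2	nodal_PTCL_TFH	5	1
TET2	PTCL_NOS_TFH	19	3
RHOA	AITL	33	9
RHOA	nodal_PTCL_TFH	5	1
RHOA	PTCL_NOS_TFH	3	0
DNMT3A	AITL	11	6
DNMT3A	nodal_PTCL_TFH	1	1
DNMT3A	PTCL_NOS_TFH	11	0
IDH2	AITL	13	4
IDH2	nodal_PTCL_TFH	0	0
IDH2	PTCL_NOS_TFH	0	0
NAV2	AITL	0	0
NAV2	nodal_PTCL_TFH	0	0
NAV2	PTCL_NOS_TFH	4	1
ODZ1	AITL	2	1
ODZ1	nodal_PTCL_TFH	1	0
ODZ1	PTCL_NOS_TFH	1	0
COL19A1	AITL	1	1
COL19A1	nodal_PTCL_TFH	0	0
COL19A1	PTCL_NOS_TFH	2	1
FAT2	AITL	1	1
FAT2	nodal_PTCL_TFH	0	0
FAT2	PTCL_NOS_TFH	2	0
MTERFD3	AITL	2	1
MTERFD3	nodal_PTCL_TFH	0	0
MTERFD3	PTCL_NOS_TFH	1	0
NOTCH1	AITL	3	3
NOTCH1	nodal_PTCL_TFH	0	0
NOTCH1	PTCL_NOS_TFH	0	0
B2M	AITL	0	0
B2M	nodal_PTCL_TFH	0	0
B2M	PTCL_NOS_TFH	2	1
HMCN1	AITL	1	1
HMCN1	nodal_PTCL_TFH	0	0
HMCN1	PTCL_NOS_TFH	1	0
LAMA2	AITL	0	0
LAMA2	nodal_PTCL_TFH	0	0
LAMA2	PTCL_NOS_TFH	2	0
MLL2	AITL	0	0
MLL2	nodal_PTCL_TFH	0	0
MLL2	PTCL_NOS_TFH	2	1
TET3	AITL	2	1
TET3	nodal_PTCL_TFH	0	0
TET3	PTCL_NOS_TFH	0	0
LYN	AITL	2	1
LYN	nodal_PTCL_TFH	0	0
LYN	PTCL_NOS_TFH	0	0
EBF2	AITL	1	0
EBF2	nodal_PTCL_TFH	0	0
EBF2	PTCL_NOS_TFH	1	0
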