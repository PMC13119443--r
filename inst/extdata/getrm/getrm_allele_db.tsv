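gene	allele	defining_variants
CYP1A2	*1	.
CYP1A2	*10	chr1:1020:G:A
CYP1A2	*2	chr1:1010:G:A
CYP2B6	*1	.
CYP2B6	*10	chr2:1020:G:A
CYP2B6	*2	chr2:1010:G:A
CYP2C19	*1	.
CYP2C19	*10	chr4:1020:G:A
CYP2C19	*2	chr4:1010:G:A
CYP2C9	*1	.
CYP2C9	*10	chr3:1020:G:A
CYP2C9	*2	chr3:1010:G:A
CYP2D6	*1	.
CYP2D6	*10	chr5:1020:G:A
CYP2D6	*2	chr5:1010:G:A
CYP2D6	*2.001	chr5:1010:G:A
CYP3A4	*1	.
CYP3A4	*2	chr6:1010:G:A
CYP3A4	*2.001	chr6:1010:G:A
CYP3A4	*4	chr6:1030:G:A
CYP3A5	*1	.
CYP3A5	*2	chr7:1010:G:A
CYP3A5	*2.001	chr7:1010:G:A
CYP3A5	*4	chr7:1030:G:A
CYP4F2	*1	.
CYP4F2	*2	chr8:1010:G:A
CYP4F2	*2.001	chr8:1010:G:A
CYP4F2	*4	chr8:1030:G:A
DPYD	*1	.
DPYD	*2	chr9:1010:G:A
DPYD	*2.001	chr9:1010:G:A
DPYD	*4	chr9:1030:G:A
HLA-A	*1	.
HLA-A	*10	chr15:1020:G:A
HLA-A	*2	chr15:1010:G:A
HLA-B	*1	.
HLA-B	*10	chr16:1020:G:A
HLA-B	*2	chr16:1010:G:A
NAT2	*1	.
NAT2	*2	chr10:1010:G:A
NAT2	*2.001	chr10:1010:G:A
NAT2	*4	chr10:1030:G:A
SLCO1B1	*1	.
SLCO1B1	*2	chr11:1010:G:A
SLCO1B1	*2.001	chr11:1010:G:A
TPMT	*1	.
TPMT	*10	chr12:1020:G:A
TPMT	*2	chr12:1010:G:A
UGT1A1	*1	.
UGT1A1	*10	chr13:1020:G:A
UGT1A1	*2	chr13:1010:G:A
VKORC1	*1	.
VKORC1	*10	chr14:1020:G:A
VKORC1	*2	chr14:1010:G:A
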