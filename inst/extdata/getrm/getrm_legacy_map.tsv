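gene	allele	defining_variants
CYP1A2	*2	chr1:1010:G:A
CYP2B6	*2	chr2:1010:G:A
CYP2C9	*2	chr3:1010:G:A
CYP2C19	*2	chr4:1010:G:A
CYP2D6	*2	chr5:1010:G:A
CYP3A4	*2	chr6:1010:G:A
CYP3A5	*2	chr7:1010:G:A
CYP4F2	*2	chr8:1010:G:A
DPYD	*2	chr9:1010:G:A
NAT2	*2	chr10:1010:G:A
SLCO1B1	*2	chr11:1010:G:A
TPMT	*2	chr12:1010:G:A
UGT1A1	*2	chr13:1010:G:A
VKORC1	*2	chr14:1010:G:A
HLA-A	*2	chr15:1010:G:A
HLA-B	*2	chr16:1010:G:A
TPMT	*36	chr12:1020:G:A
UGT1A1	*36	chr13:1020:G:A
VKORC1	*36	chr14:1020:G:A
HLA-A	*36	chr15:1020:G:A
HLA-B	*36	chr16:1020:G:A
CYP1A2	*36	chr1:1020:G:A
CYP2B6	*36	chr2:1020:G:A
CYP2C9	*36	chr3:1020:G:A
CYP2C19	*36	chr4:1020:G:A
CYP2D6	*36	chr5:1020:G:A
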