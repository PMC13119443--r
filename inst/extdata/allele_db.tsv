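gene	allele	defining_variants
CYP2B6	*1	.
CYP2B6	*4	chr19:41515263:A:G
CYP2B6	*6	chr19:41512841:G:T;chr19:41515263:A:G
CYP2B6	*9	chr19:41512841:G:T
CYP2C19	*1	.
CYP2C19	*2	chr10:96541616:G:A
CYP2C19	*17	chr10:96521657:C:T
CYP2C9	*1	.
CYP2C9	*2	chr10:96702047:C:T
CYP2C9	*3	chr10:96741053:A:C
CYP2D6	*1	.
CYP2D6	*4	chr22:42524947:C:T
CYP2D6	*10	chr22:42526694:C:T
CYP2D6	*41	chr22:42523805:G:A
CYP3A5	*1	.
CYP3A5	*3	chr7:99270539:T:C
DPYD	*1	.
DPYD	*2A	chr1:97915614:C:T
NUDT15	*1	.
NUDT15	*3	chr13:48619855:C:T
SLCO1B1	*1	.
SLCO1B1	*5	chr12:21331549:T:C
TPMT	*1	.
TPMT	*3C	chr6:18130918:A:G
UGT1A1	*1	.
UGT1A1	*6	chr2:234669144:G:A
VKORC1	*1	.
VKORC1	*2	chr16:31107689:G:A
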