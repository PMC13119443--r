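gene	category	chrom	start	end	strategy
ABCG2	priority	chr4	89011416	89152474	full
CACNA1S	priority	chr1	201008640	201081694	full
CYP2B6	priority	chr19	41497204	41524301	full
CYP2C19	priority	chr10	96519437	96612671	full
CYP2C9	priority	chr10	96698415	96749147	full
CYP2D6	priority	chr22	42522501	42526883	haplotype
CYP3A4	priority	chr7	99354604	99381888	full
CYP3A5	priority	chr7	99245813	99277621	full
CYP4F2	priority	chr19	15988833	16008884	full
DPYD	priority	chr1	97543300	98386615	full
F5	priority	chr1	169481192	169555768	full
G6PD	priority	chrX	153759606	153775787	full
HLA-A	priority	chr6	29910247	29913661	haplotype
HLA-B	priority	chr6	31321649	31324989	haplotype
IFNL3	priority	chr19	39734896	39738646	full
NUDT15	priority	chr13	48611703	48621358	full
RYR1	priority	chr19	38924340	39078204	full
SLCO1B1	priority	chr12	21284128	21392730	full
TPMT	priority	chr6	18128542	18155374	full
UGT1A1	priority	chr2	234668879	234681945	full
VKORC1	priority	chr16	31102175	31109000	full
ABCC3	secondary	chr17	48712218	48769063	full
CALU	secondary	chr7	128379262	128411960	full
COMT	secondary	chr22	19929263	19957498	full
CYP1A2	secondary	chr15	75041185	75048543	full
CYP2C18	secondary	chr10	96443252	96495947	full
GGCX	secondary	chr2	85776905	85788947	full
NAT2	secondary	chr8	18248755	18258728	full
RARG	secondary	chr12	53604352	53614197	full
SLC28A3	secondary	chr9	86890563	86966588	full
UGT1A6	secondary	chr2	234601669	234685000	full
ABCB1	candidate	chr7	87132948	87342564	hotspot
CES1	candidate	chr16	55836764	55867075	hotspot
CYP2A6	candidate	chr19	41349443	41356352	hotspot
POR	candidate	chr7	75544419	75616173	hotspot
SLC22A1	candidate	chr6	160542821	160579750	hotspot
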