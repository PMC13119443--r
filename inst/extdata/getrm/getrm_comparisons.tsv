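sample	gene	reference_allele	test_allele	category
S001	CYP1A2	*2	*2	concordant
S002	CYP2B6	*1	*1	concordant
S003	CYP2C9	*2	*2	concordant
S004	CYP2C19	*1	*1	concordant
S005	CYP2D6	*2	*2	concordant
S006	CYP3A4	*1	*1	concordant
S007	CYP3A5	*2	*2	concordant
S008	CYP4F2	*1	*1	concordant
S009	DPYD	*2	*2	concordant
S010	NAT2	*1	*1	concordant
S011	SLCO1B1	*2	*2	concordant
S012	TPMT	*1	*1	concordant
S013	UGT1A1	*2	*2	concordant
S014	VKORC1	*1	*1	concordant
S015	HLA-A	*2	*2	concordant
S016	HLA-B	*1	*1	concordant
S017	CYP1A2	*2	*2	concordant
S018	CYP2B6	*1	*1	concordant
S019	CYP2C9	*2	*2	concordant
S020	CYP2C19	*1	*1	concordant
S021	CYP2D6	*2	*2	concordant
S022	CYP3A4	*1	*1	concordant
S023	CYP3A5	*2	*2	concordant
S024	CYP4F2	*1	*1	concordant
S025	DPYD	*2	*2	concordant
S026	NAT2	*1	*1	concordant
S027	SLCO1B1	*2	*2	concordant
S028	TPMT	*1	*1	concordant
S029	UGT1A1	*2	*2	concordant
S030	VKORC1	*1	*1	concordant
S031	HLA-A	*2	*2	concordant
S032	HLA-B	*1	*1	concordant
S033	CYP1A2	*2	*2	concordant
S034	CYP2B6	*1	*1	concordant
S035	CYP2C9	*2	*2	concordant
S036	CYP2C19	*1	*1	concordant
S037	CYP2D6	*2	*2	concordant
S038	CYP3A4	*1	*1	concordant
S039	CYP3A5	*2	*2	concordant
S040	CYP4F2	*1	*1	concordant
S041	DPYD	*2	*2	concordant
S042	NAT2	*1	*1	concordant
S043	SLCO1B1	*2	*2	concordant
S044	TPMT	*1	*1	concordant
S045	UGT1A1	*2	*2	concordant
S046	VKORC1	*1	*1	concordant
S047	HLA-A	*2	*2	concordant
S048	HLA-B	*1	*1	concordant
S049	CYP1A2	*2	*2	concordant
S050	CYP2B6	*1	*1	concordant
S051	CYP2C9	*2	*2	concordant
S052	CYP2C19	*1	*1	concordant
S053	CYP2D6	*2	*2	concordant
S054	CYP3A4	*1	*1	concordant
S055	CYP3A5	*2	*2	concordant
S056	CYP4F2	*1	*1	concordant
S057	DPYD	*2	*2	concordant
S058	NAT2	*1	*1	concordant
S059	SLCO1B1	*2	*2	concordant
S060	TPMT	*1	*1	concordant
S061	UGT1A1	*2	*2	concordant
S062	VKORC1	*1	*1	concordant
S063	HLA-A	*2	*2	concordant
S064	HLA-B	*1	*1	concordant
S065	CYP1A2	*2	*2	concordant
S066	CYP2B6	*1	*1	concordant
S067	CYP2C9	*2	*2	concordant
S068	CYP2C19	*1	*1	concordant
S069	CYP2D6	*2	*2	concordant
S070	CYP3A4	*1	*1	concordant
S071	CYP3A5	*2	*2	concordant
S072	CYP4F2	*1	*1	concordant
S073	DPYD	*2	*2	concordant
S074	NAT2	*1	*1	concordant
S075	SLCO1B1	*2	*2	concordant
S076	TPMT	*1	*1	concordant
S077	UGT1A1	*2	*2	concordant
S078	VKORC1	*1	*1	concordant
S079	HLA-A	*2	*2	concordant
S080	HLA-B	*1	*1	concordant
S081	CYP1A2	*2	*2	concordant
S082	CYP2B6	*1	*1	concordant
S083	CYP2C9	*2	*2	concordant
S084	CYP2C19	*1	*1	concordant
S085	CYP2D6	*2	*2	concordant
S086	CYP3A4	*1	*1	concordant
S087	CYP3A5	*2	*2	concordant
S088	CYP4F2	*1	*1	concordant
S089	DPYD	*2	*2	concordant
S090	NAT2	*1	*1	concordant
S091	SLCO1B1	*2	*2	concordant
S092	TPMT	*1	*1	concordant
S093	UGT1A1	*2	*2	concordant
S094	VKORC1	*1	*1	concordant
S095	HLA-A	*2	*2	concordant
S096	HLA-B	*1	*1	concordant
S097	CYP1A2	*2	*2	concordant
S098	CYP2B6	*1	*1	concordant
S099	CYP2C9	*2	*2	concordant
S100	CYP2C19	*1	*1	concordant
S101	CYP2D6	*2	*2	concordant
S102	CYP3A4	*1	*1	concordant
S103	CYP3A5	*2	*2	concordant
S104	CYP4F2	*1	*1	concordant
S105	DPYD	*2	*2	concordant
S106	NAT2	*1	*1	concordant
S107	SLCO1B1	*2	*2	concordant
S108	TPMT	*1	*1	concordant
S109	UGT1A1	*2	*2	concordant
S110	VKORC1	*1	*1	concordant
S111	HLA-A	*2	*2	concordant
S112	HLA-B	*1	*1	concordant
S113	CYP1A2	*2	*2	concordant
S114	CYP2B6	*1	*1	concordant
S115	CYP2C9	*2	*2	concordant
S116	CYP2C19	*1	*1	concordant
S117	CYP2D6	*2	*2	concordant
S118	CYP3A4	*1	*1	concordant
S119	CYP3A5	*2	*2	concordant
S120	CYP4F2	*1	*1	concordant
S121	DPYD	*2	*2	concordant
S122	NAT2	*1	*1	concordant
S123	SLCO1B1	*2	*2	concordant
S124	TPMT	*1	*1	concordant
S125	UGT1A1	*2	*2	concordant
S126	VKORC1	*1	*1	concordant
S127	HLA-A	*2	*2	concordant
S128	HLA-B	*1	*1	concordant
S129	CYP1A2	*2	*2	concordant
S130	CYP2B6	*1	*1	concordant
S131	CYP2C9	*2	*2	concordant
S132	CYP2C19	*1	*1	concordant
S133	CYP2D6	*2	*2	concordant
S134	CYP3A4	*1	*1	concordant
S135	CYP3A5	*2	*2	concordant
S136	CYP4F2	*1	*1	concordant
S137	DPYD	*2	*2	concordant
S138	NAT2	*1	*1	concordant
S139	SLCO1B1	*2	*2	concordant
S140	TPMT	*1	*1	concordant
S141	UGT1A1	*2	*2	concordant
S142	VKORC1	*1	*1	concordant
S143	HLA-A	*2	*2	concordant
S144	HLA-B	*1	*1	concordant
S145	CYP1A2	*2	*2	concordant
S146	CYP2B6	*1	*1	concordant
S147	CYP2C9	*2	*2	concordant
S148	CYP2C19	*1	*1	concordant
S149	CYP2D6	*2	*2	concordant
S150	CYP3A4	*1	*1	concordant
S151	CYP3A5	*2	*2	concordant
S152	CYP4F2	*1	*1	concordant
S153	DPYD	*2	*2	concordant
S154	NAT2	*1	*1	concordant
S155	SLCO1B1	*2	*2	concordant
S156	TPMT	*1	*1	concordant
S157	UGT1A1	*2	*2	concordant
S158	VKORC1	*1	*1	concordant
S159	HLA-A	*2	*2	concordant
S160	HLA-B	*1	*1	concordant
S161	CYP1A2	*2	*2	concordant
S162	CYP2B6	*1	*1	concordant
S163	CYP2C9	*2	*2	concordant
S164	CYP2C19	*1	*1	concordant
S165	CYP2D6	*2	*2	concordant
S166	CYP3A4	*1	*1	concordant
S167	CYP3A5	*2	*2	concordant
S168	CYP4F2	*1	*1	concordant
S169	DPYD	*2	*2	concordant
S170	NAT2	*1	*1	concordant
S171	SLCO1B1	*2	*2	concordant
S172	TPMT	*1	*1	concordant
S173	UGT1A1	*2	*2	concordant
S174	VKORC1	*1	*1	concordant
S175	HLA-A	*2	*2	concordant
S176	HLA-B	*1	*1	concordant
S177	CYP1A2	*2	*2	concordant
S178	CYP2B6	*1	*1	concordant
S179	CYP2C9	*2	*2	concordant
S180	CYP2C19	*1	*1	concordant
S181	CYP2D6	*2	*2	concordant
S182	CYP3A4	*1	*1	concordant
S183	CYP3A5	*2	*2	concordant
S184	CYP4F2	*1	*1	concordant
S185	DPYD	*2	*2	concordant
S186	NAT2	*1	*1	concordant
S187	SLCO1B1	*2	*2	concordant
S188	TPMT	*1	*1	concordant
S189	UGT1A1	*2	*2	concordant
S190	VKORC1	*1	*1	concordant
S191	HLA-A	*2	*2	concordant
S192	HLA-B	*1	*1	concordant
S193	CYP1A2	*2	*2	concordant
S194	CYP2B6	*1	*1	concordant
S195	CYP2C9	*2	*2	concordant
S196	CYP2C19	*1	*1	concordant
S197	CYP2D6	*2	*2	concordant
S198	CYP3A4	*1	*1	concordant
S199	CYP3A5	*2	*2	concordant
S200	CYP4F2	*1	*1	concordant
S201	DPYD	*2	*2	concordant
S202	NAT2	*1	*1	concordant
S203	SLCO1B1	*2	*2	concordant
S204	TPMT	*1	*1	concordant
S205	UGT1A1	*2	*2	concordant
S206	VKORC1	*1	*1	concordant
S207	HLA-A	*2	*2	concordant
S208	HLA-B	*1	*1	concordant
S209	CYP1A2	*2	*2	concordant
S210	CYP2B6	*1	*1	concordant
S211	CYP2C9	*2	*2	concordant
S212	CYP2C19	*1	*1	concordant
S213	CYP2D6	*2	*2	concordant
S214	CYP3A4	*1	*1	concordant
S215	CYP3A5	*2	*2	concordant
S216	CYP4F2	*1	*1	concordant
S217	DPYD	*2	*2	concordant
S218	NAT2	*1	*1	concordant
S219	SLCO1B1	*2	*2	concordant
S220	TPMT	*1	*1	concordant
S221	UGT1A1	*2	*2	concordant
S222	VKORC1	*1	*1	concordant
S223	HLA-A	*2	*2	concordant
S224	HLA-B	*1	*1	concordant
S225	CYP1A2	*2	*2	concordant
S226	CYP2B6	*1	*1	concordant
S227	CYP2C9	*2	*2	concordant
S228	CYP2C19	*1	*1	concordant
S229	CYP2D6	*2	*2.001	test_only_allele
S230	CYP3A4	*2	*2.001	test_only_allele
S231	CYP3A5	*2	*2.001	test_only_allele
S232	CYP4F2	*2	*2.001	test_only_allele
S233	DPYD	*2	*2.001	test_only_allele
S234	NAT2	*2	*2.001	test_only_allele
S235	SLCO1B1	*2	*2.001	test_only_allele
S236	TPMT	*36	*10	reference_only_allele
S237	UGT1A1	*36	*10	reference_only_allele
S238	VKORC1	*36	*10	reference_only_allele
S239	HLA-A	*36	*10	reference_only_allele
S240	HLA-B	*36	*10	reference_only_allele
S241	CYP1A2	*36	*10	reference_only_allele
S242	CYP2B6	*36	*10	reference_only_allele
S243	CYP2C9	*36	*10	reference_only_allele
S244	CYP2C19	*36	*10	reference_only_allele
S245	CYP2D6	*36	*10	reference_only_allele
S246	CYP3A4	*4	*1	discordant
S247	CYP3A5	*4	*1	discordant
S248	CYP4F2	*4	*1	discordant
S249	DPYD	*4	*1	discordant
S250	NAT2	*4	*1	discordant
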