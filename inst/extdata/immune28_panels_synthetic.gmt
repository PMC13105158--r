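Activated CD8 T cell	synthetic placeholder markers	IMM0324	IMM0167	IMM0129	IMM0299	IMM0270	IMM0187	IMM0307	IMM0085	IMM0277	IMM0362
Central memory CD8 T cell	synthetic placeholder markers	IMM0330	IMM0263	IMM0329	IMM0079	IMM0213	IMM0037	IMM0105	IMM0217	IMM0366	IMM0165
Effector memory CD8 T cell	synthetic placeholder markers	IMM0290	IMM0362	IMM0382	IMM0089	IMM0289	IMM0340	IMM0326	IMM0330	IMM0042	IMM0111
Activated CD4 T cell	synthetic placeholder markers	IMM0020	IMM0044	IMM0377	IMM0343	IMM0070	IMM0121	IMM0040	IMM0172	IMM0025	IMM0375
Central memory CD4 T cell	synthetic placeholder markers	IMM0248	IMM0198	IMM0378	IMM0039	IMM0298	IMM0390	IMM0280	IMM0160	IMM0014	IMM0130
Effector memory CD4 T cell	synthetic placeholder markers	IMM0045	IMM0022	IMM0206	IMM0230	IMM0193	IMM0371	IMM0104	IMM0326	IMM0255	IMM0393
T follicular helper cell	synthetic placeholder markers	IMM0104	IMM0103	IMM0331	IMM0013	IMM0296	IMM0217	IMM0176	IMM0345	IMM0279	IMM0110
Gamma delta T cell	synthetic placeholder markers	IMM0084	IMM0359	IMM0029	IMM0141	IMM0252	IMM0221	IMM0108	IMM0304	IMM0033	IMM0045
Type 1 T helper cell	synthetic placeholder markers	IMM0149	IMM0287	IMM0102	IMM0145	IMM0329	IMM0343	IMM0339	IMM0118	IMM0346	IMM0304
Type 17 T helper cell	synthetic placeholder markers	IMM0107	IMM0064	IMM0224	IMM0103	IMM0316	IMM0051	IMM0221	IMM0290	IMM0138	IMM0129
Type 2 T helper cell	synthetic placeholder markers	IMM0299	IMM0282	IMM0143	IMM0285	IMM0170	IMM0048	IMM0204	IMM0295	IMM0024	IMM0181
Regulatory T cell	synthetic placeholder markers	IMM0214	IMM0296	IMM0225	IMM0339	IMM0346	IMM0163	IMM0043	IMM0001	IMM0029	IMM0078
Activated B cell	synthetic placeholder markers	IMM0326	IMM0284	IMM0116	IMM0233	IMM0293	IMM0061	IMM0369	IMM0086	IMM0327	IMM0110
Immature B cell	synthetic placeholder markers	IMM0355	IMM0307	IMM0300	IMM0049	IMM0361	IMM0316	IMM0242	IMM0246	IMM0305	IMM0306
Memory B cell	synthetic placeholder markers	IMM0247	IMM0239	IMM0219	IMM0135	IMM0111	IMM0020	IMM0377	IMM0051	IMM0053	IMM0356
Natural killer cell	synthetic placeholder markers	IMM0130	IMM0304	IMM0065	IMM0300	IMM0359	IMM0105	IMM0124	IMM0077	IMM0218	IMM0098
CD56bright natural killer cell	synthetic placeholder markers	IMM0194	IMM0019	IMM0273	IMM0031	IMM0355	IMM0174	IMM0237	IMM0075	IMM0016	IMM0040
CD56dim natural killer cell	synthetic placeholder markers	IMM0265	IMM0306	IMM0092	IMM0122	IMM0152	IMM0138	IMM0207	IMM0249	IMM0160	IMM0229
Myeloid derived suppressor cell	synthetic placeholder markers	IMM0140	IMM0126	IMM0014	IMM0116	IMM0016	IMM0271	IMM0130	IMM0065	IMM0358	IMM0273
Natural killer T cell	synthetic placeholder markers	IMM0212	IMM0127	IMM0133	IMM0041	IMM0364	IMM0373	IMM0328	IMM0036	IMM0305	IMM0297
Activated dendritic cell	synthetic placeholder markers	IMM0064	IMM0129	IMM0309	IMM0212	IMM0362	IMM0344	IMM0117	IMM0398	IMM0102	IMM0050
Plasmacytoid dendritic cell	synthetic placeholder markers	IMM0336	IMM0286	IMM0254	IMM0349	IMM0386	IMM0072	IMM0382	IMM0078	IMM0168	IMM0328
Immature dendritic cell	synthetic placeholder markers	IMM0116	IMM0356	IMM0113	IMM0234	IMM0121	IMM0073	IMM0027	IMM0041	IMM0015	IMM0294
Macrophage	synthetic placeholder markers	IMM0062	IMM0390	IMM0132	IMM0035	IMM0381	IMM0355	IMM0077	IMM0105	IMM0185	IMM0327
Eosinophil	synthetic placeholder markers	IMM0153	IMM0031	IMM0037	IMM0255	IMM0231	IMM0028	IMM0062	IMM0148	IMM0285	IMM0127
Mast cell	synthetic placeholder markers	IMM0298	IMM0060	IMM0284	IMM0334	IMM0031	IMM0268	IMM0093	IMM0336	IMM0300	IMM0202
Monocyte	synthetic placeholder markers	IMM0098	IMM0282	IMM0241	IMM0033	IMM0132	IMM0117	IMM0086	IMM0217	IMM0280	IMM0293
Neutrophil	synthetic placeholder markers	IMM0108	IMM0271	IMM0270	IMM0239	IMM0209	IMM0338	IMM0097	IMM0224	IMM0072	IMM0053
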