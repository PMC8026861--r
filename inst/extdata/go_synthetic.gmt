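SYNGO:0001	blood pressure regulation (synthetic)	NPPB	NPPA	IRS1	SMAD3	MIR155	ADRB1	AVP	BG0000	BG0001	BG0002	BG0003	BG0004	BG0005	BG0006	BG0007	BG0008	BG0009	BG0010	BG0011	BG0012	BG0013	BG0014	BG0015	BG0016	BG0017	BG0018	BG0019	BG0020	BG0021	BG0022	BG0023	BG0024	BG0025	BG0026	BG0027	BG0028	BG0029	BG0030	BG0031	BG0032	BG0033	BG0034	BG0035	BG0036	BG0037	BG0038	BG0039
SYNGO:0002	natriuretic peptide signaling (synthetic)	NPPA	NPPB	AVP	BG0040	BG0041	BG0042	BG0043	BG0044	BG0045	BG0046	BG0047	BG0048	BG0049	BG0050	BG0051	BG0052	BG0053	BG0054	BG0055	BG0056	BG0057	BG0058	BG0059	BG0060	BG0061	BG0062	BG0063	BG0064	BG0065	BG0066	BG0067	BG0068	BG0069
SYNGO:0003	cytoskeleton remodeling (synthetic)	ROCK1	MAPK14	COL3A1	BG0070	BG0071	BG0072	BG0073	BG0074	BG0075	BG0076	BG0077	BG0078	BG0079	BG0080	BG0081	BG0082	BG0083	BG0084	BG0085	BG0086	BG0087	BG0088	BG0089	BG0090	BG0091	BG0092	BG0093	BG0094	BG0095	BG0096	BG0097	BG0098	BG0099	BG0100	BG0101	BG0102	BG0103	BG0104	BG0105	BG0106	BG0107	BG0108	BG0109	BG0110	BG0111	BG0112	BG0113	BG0114	BG0115	BG0116	BG0117	BG0118	BG0119	BG0120	BG0121	BG0122	BG0123	BG0124	BG0125	BG0126	BG0127	BG0128	BG0129	BG0130	BG0131	BG0132	BG0133	BG0134	BG0135	BG0136	BG0137	BG0138	BG0139	BG0140	BG0141	BG0142	BG0143	BG0144	BG0145	BG0146	BG0147	BG0148	BG0149	BG0150	BG0151	BG0152	BG0153	BG0154	BG0155	BG0156	BG0157	BG0158	BG0159
SYNGO:0004	unrelated housekeeping (synthetic)	BG0160	BG0161	BG0162	BG0163	BG0164	BG0165	BG0166	BG0167	BG0168	BG0169	BG0170	BG0171	BG0172	BG0173	BG0174	BG0175	BG0176	BG0177	BG0178	BG0179	BG0180	BG0181	BG0182	BG0183	BG0184	BG0185	BG0186	BG0187	BG0188	BG0189	BG0190	BG0191	BG0192	BG0193	BG0194	BG0195	BG0196	BG0197	BG0198	BG0199	BG0200	BG0201	BG0202	BG0203	BG0204	BG0205	BG0206	BG0207	BG0208	BG0209	BG0210	BG0211	BG0212	BG0213	BG0214	BG0215	BG0216	BG0217	BG0218	BG0219	BG0220	BG0221	BG0222	BG0223	BG0224	BG0225	BG0226	BG0227	BG0228	BG0229	BG0230	BG0231	BG0232	BG0233	BG0234	BG0235	BG0236	BG0237	BG0238	BG0239	BG0240	BG0241	BG0242	BG0243	BG0244	BG0245	BG0246	BG0247	BG0248	BG0249	BG0250	BG0251	BG0252	BG0253	BG0254	BG0255	BG0256	BG0257	BG0258	BG0259	BG0260	BG0261	BG0262	BG0263	BG0264	BG0265	BG0266	BG0267	BG0268	BG0269	BG0270	BG0271	BG0272	BG0273	BG0274	BG0275	BG0276	BG0277	BG0278	BG0279	BG0280	BG0281	BG0282	BG0283	BG0284	BG0285	BG0286	BG0287	BG0288	BG0289	BG0290	BG0291	BG0292	BG0293	BG0294	BG0295	BG0296	BG0297	BG0298	BG0299	BG0300	BG0301	BG0302	BG0303	BG0304	BG0305	BG0306	BG0307	BG0308	BG0309	BG0310	BG0311	BG0312	BG0313	BG0314	BG0315	BG0316	BG0317	BG0318	BG0319	BG0320	BG0321	BG0322	BG0323	BG0324	BG0325	BG0326	BG0327	BG0328	BG0329	BG0330	BG0331	BG0332	BG0333	BG0334	BG0335	BG0336	BG0337	BG0338	BG0339	BG0340	BG0341	BG0342	BG0343	BG0344	BG0345	BG0346	BG0347	BG0348	BG0349	BG0350	BG0351	BG0352	BG0353	BG0354	BG0355	BG0356	BG0357	BG0358	BG0359
SYNGO:0005	insulin signaling (synthetic)	IRS1	SMAD3	BG0360	BG0361	BG0362	BG0363	BG0364	BG0365	BG0366	BG0367	BG0368	BG0369	BG0370	BG0371	BG0372	BG0373	BG0374	BG0375	BG0376	BG0377	BG0378	BG0379	BG0380	BG0381	BG0382	BG0383	BG0384	BG0385	BG0386	BG0387	BG0388	BG0389	BG0390	BG0391	BG0392	BG0393	BG0394	BG0395	BG0396	BG0397	BG0398	BG0399	BG0000	BG0001	BG0002	BG0003	BG0004	BG0005	BG0006	BG0007	BG0008	BG0009	BG0010	BG0011	BG0012	BG0013	BG0014	BG0015	BG0016	BG0017	BG0018	BG0019
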