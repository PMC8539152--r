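name	smiles	hc_exp	hc_calc_ref	dev_pct_ref
1,1,3,3-Tetramethylguanidinium nitrate	CN(C)C(=[NH2+])N(C)C.[O-][N+]([O-])=O	-3656.5	-3656.5	0.00
1-Butyl-1-methylpyrrolidinium dicyanamide	CCCC[N+]1(C)CCCC1.N#C[N-]C#N	-7244.8	-7250.1	-0.07
1-Butyl-3-methylimidazolium chloride	CCCCn1cc[n+](C)c1.[Cl-]	-5232.3	-5206.6	0.49
1-Butyl-3-methylimidazolium dicyanoamide	CCCCn1cc[n+](C)c1.N#C[N-]C#N	-6273.9	-6271.6	0.04
1-Butyl-3-methylimidazolium nitrate	CCCCn1cc[n+](C)c1.[O-][N+]([O-])=O	-5013.2	-5017.8	-0.09
1-Decyl-3-methylimidazolium bromide	CCCCCCCCCCn1cc[n+](C)c1.[Br-]	-9105.2	-9127.4	-0.24
1-Dodecyl-3-methylimidazolium bromide	CCCCCCCCCCCCn1cc[n+](C)c1.[Br-]	-10406.0	-10434.4	-0.27
1-Ethanol-3-methyl-imidazolium dicyanoamide	OCCn1cc[n+](C)c1.N#C[N-]C#N	-4793.0	-4780.7	0.26
1-Ethyl-3-methylimidazolium chloride	CCn1cc[n+](C)c1.[Cl-]	-3886.2	-3899.7	-0.35
1-Ethyl-3-methylimidazolium dicyanamide	CCn1cc[n+](C)c1.N#C[N-]C#N	-4955.4	-4964.7	-0.19
1-Ethyl-3-methylimidazolium nitrate	CCn1cc[n+](C)c1.[O-][N+]([O-])=O	-3697.5	-3710.9	-0.36
1-Methyl-3-pentylimidazolium chloride	CCCCCn1cc[n+](C)c1.[Cl-]	-5904.3	-5860.1	0.75
1-Octyl-3-methylimidazolium bromide	CCCCCCCCn1cc[n+](C)c1.[Br-]	-7837.8	-7820.5	0.22
1-Tetradecyl-3-methylimidazolium bromide	CCCCCCCCCCCCCCn1cc[n+](C)c1.[Br-]	-11718.0	-11741.3	-0.20
6,6-(Tetramethylene-3'-oxa)-7a-(nitroxymethyl)-3-oxoperhydroimidazo[1,5-c]oxazol-6-ium nitrate	O=C1OCC2(CO[N+]([O-])=O)C[N+]3(CCOCC3)CN12.[O-][N+]([O-])=O	-5384.8	-5376.5	0.15
6,6-(Tetramethylene-3'-oxa)-7a-methyl-3-oxoperhydroimidazo[1,5-c]oxazol-6-ium nitrate	O=C1OCC2(C)C[N+]3(CCOCC3)CN12.[O-][N+]([O-])=O	-5587.5	-5604.8	-0.31
6,6-Pentamethylene-7a-(nitroxymethyl)-3-oxoperhydroimidazo[1,5-c]oxazol-6-ium nitrate	O=C1OCC2(CO[N+]([O-])=O)C[N+]3(CCCCC3)CN12.[O-][N+]([O-])=O	-6166.4	-6159.0	0.12
Diethylammonium diethyldithiocarbamate	CC[NH2+]CC.CCN(CC)C([S-])=S	-7639.6	-7650.0	-0.14
Diisobutylammonium diisobutyldithiocarbamate	CC(C)C[NH2+]CC(C)C.CC(C)CN(CC(C)C)C([S-])=S	-12891.0	-12868.4	0.18
Diisopropylammonium diisopropyldithiocarbamate	CC(C)[NH2+]C(C)C.CC(C)N(C(C)C)C([S-])=S	-10260.0	-10252.6	0.07
Dipropylammonium dipropyldithiocarbamate	CCC[NH2+]CCC.CCCN(CCC)C([S-])=S	-10252.0	-10271.7	-0.19
N,N-Dimethylglycine bisulfate	C[NH+](C)CC(O)=O.OS(=O)(=O)[O-]	-2610.6	-2604.7	0.23
N,N-Dimethylglycine methyl ester bisulfate	C[NH+](C)CC(=O)OC.OS(=O)(=O)[O-]	-3323.2	-3329.1	-0.18
N,N-Dimethylglycine methyl ester sulfate	C[NH+](C)CC(=O)OC.C[NH+](C)CC(=O)OC.[O-]S(=O)(=O)[O-]	-6765.2	-6790.2	-0.37
N,N-Dimethylglycine sulfate	C[NH+](C)CC(O)=O.C[NH+](C)CC(O)=O.[O-]S(=O)(=O)[O-]	-5371.6	-5346.6	0.47
Tetraethylammonium nitrate	CC[N+](CC)(CC)CC.[O-][N+]([O-])=O	-5573.4	-5590.6	-0.31
Tetramethylammonium nitrate	C[N+](C)(C)C.[O-][N+]([O-])=O	-2960.5	-2958.5	0.07
Tetra-n-butylammonium nitrate	CCCC[N+](CCCC)(CCCC)CCCC.[O-][N+]([O-])=O	-10841.0	-10818.4	0.21
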