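cytoband	start_bp	end_bp	size_mb_printed	cn_range	cell_lines	correlated_genes
2p11.2	88741497	89240742	0.5	0.2-1.1	Colo201;Colo320DM;HCT116;HCT116 p53-/-;HT29;LS411N;LoVo;NCI H508;NCI H716;SK-CO-1;SW480;SW837;T84	
3q26.32	180172618	180364415	0.02	0.2-0.6	Colo320DM;HT29;LS411N;NCI H508;NCI H716;SW480;T84	
3q27.1	185357499	185500005	0.14	0.2-1.2	Colo201;Colo320DM;HT29;LS411N;NCI H508;SW480;T84	
3q28	190361018	190756766	0.4	0.2-0.7	Colo320DM;HCT116;HCT116 p53-/-;HT29;LS411N;NCI H508;SW480;T84	
3q29	198737465	198973765	0.24	0.2-0.7	Colo201;Colo320DM;HT29;LS411N;NCI H508;SW480;T84	
5p15.33-p14.1	144656	25059988	24.92	0.2-0.7	Colo201;HT29;LS411N;LoVo;NCI H508;NCI H716;SK-CO-1;SW480	PDCD6
7p22.3	959839	1554223	0.59	0.3-0.8	Colo201;LoVo;NCI H508;NCI H716;SW48;SW480;T84	
7p21.3	10059941	10462006	0.40	0.2-1.1	DLD-1;LoVo;NCI H508;NCI H716;SW48;SW480;T84	
7p21.1-p14.2	19159609	36992541	13.35	0.3-0.9	Colo201;LS411N;LoVo;NCI H508;NCI H716;SW48;SW480;T84	CYCS;TOMM7;MIR196B;NOD1
7p14.2-p11.2	37182752	56225015	19.04	0.2-0.6	Colo201;LS411N;LoVo;NCI H508;NCI H716;SK-CO-1;SW48;SW480;T84	MRPL32;DDX56;PURB;TBRG4;COBL;LANCL2;MRPS17
7q11.22	69497636	71538673	2.04	0.2-0.3	LS411N;LoVo;NCI H508;SK-CO-1;SW48;SW480;T84	
7q11.23-q31.1	76596876	110404588	33.81	0.2-1.1	Colo201;DLD-1;HT29;LS411N;LoVo;NCI H508;NCI H716;SK-CO-1;SW48;SW480;T84	TMEM60;CLDN12;SHFM1;LMTK2;PTCD1;PLOD3;ZNHIT1;ARMC10;RINT1;BCAP29;SLC26A4
7q31.1-q31.31	110930968	119328807	8.4	0.2-0.6	LS411N;LoVo;NCI H508;NCI H716;SK-CO-1;SW48;T84	ST7
7q31.33-q34	124724896	138981311	14.26	0.2-1.0	Colo201;HCT116 p53-/-;LS411N;LoVo;NCI H508;NCI H716;SK-CO-1;SW48	IMPDH1;CHCHD3;NUP205;KIAA1549;LUC7L2
7q35	146954947	147418309	0.46	0.2-0.6	Colo201;LoVo;NCI H508;NCI H716;SK-CO-1;SW48;T84	
8q24.13-q24.21	126328971	128964088	1.46	0.3-4.2	Colo201;Colo320DM;HCT116;HCT116 p53-/-;HT29;NCI H716;SK-CO-1;SW480;SW837	NSMCE2;TRIB1;FAM84B;LOC727677;MIR1204;MYC
8q24.21	129068127	129110839	0.04	0.3-3.4	Colo201;Colo320DM;HCT116;HCT116 p53-/-;HT29;SK-CO-1;SW480	
12p13.3	33393	185534	0.15	0.2-0.6	Colo201;LS411N;LoVo;NCI H716;SW480;SW837;T84	
12p12.3-p12.2	15652223	20311064	4.66	0.2-1.5	Colo320DM;LS411N;LoVo;NCI H716;SK-CO-1;SW480;SW837;T84	STRAP;AEBP2
13q12.11-q13.3	18761622	35141488	16.38	0.2-3.39	Colo201;Colo320DM;HT29;LS411N;NCI H508;NCI H716;SK-CO-1;SW480	MPHOSP8;N6AMT2;XPO4;GTF3A;MTIF3;POMP;UBL3;BRCA2;PDS5B;RFC3
13q14.11	42472749	42745298	0.27	0.2-0.8	Colo201;Colo320DM;DLD-1;HT29;LS411N;NCI H508;SW480	
14q32.33	105305751	106342077	1.04	0.4-1.3	Colo201;Colo320DM;HCT116;HCT116 p53-/-;HT29;LS411N;LoVo;NCI H508;NCI H716;SK-CO-1;SW48;SW480;SW837;T84	
17q24.1	61037879	61181176	0.14	0.2-0.7	Colo201;Colo320DM;HCT116;HCT116 p53-/-;HT29;NCI H508;SW837	
17q25.1	70481449	70707547	0.23	0.3-1.0	Colo201;HCT116;HCT116 p53-/-;NCI H508;NCI H716;SK-CO-1;SW837	
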