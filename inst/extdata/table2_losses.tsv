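cytoband	start_bp	end_bp	size_mb_printed	cn_range	cell_lines	genes_note
2q23.3	152128419	152319262	0.2	-0.3 to -0.65	Colo201;Colo320DM;LS411N;NCI H508;SK-CO-1;SW480;T84	NEB
3p14.2	60179044	60195847	0.02	-0.3 to -1.6	Colo201;HCT116 p53-/-;HT29;LS411N;NCI H508;NCI H716;SW837	Intron of FHIT
3p14.2	60195847	60211085	0.02	-0.3 to -1.6	Colo201;HCT116;HCT116 p53-/-;HT29;LS411N;NCI H508;NCI H716;SW837	Intron of FHIT
3p14.2	60211085	60366651	0.2	-0.3 to -3.0	Colo201;HCT116;HCT116 p53-/-;HT29;LS411N;LoVo;NCI H508;NCI H716;SW837	Intron of FHIT
3p14.2	60366651	60600423	0.2	-0.3 to -3.0	Colo201;HCT116 p53-/-;HT29;LS411N;LoVo;NCI H508;NCI H716;SW480;SW837	FHIT
3p14.2	60600423	60601597	0.001	-0.3 to -2.2	Colo201;HCT116 p53-/-;HT29;LS411N;LoVo;NCI H508;NCI H716;SW837	Intron of FHIT
3p14.2	60601597	60659727	0.06	-0.3 to -2.2	Colo201;Colo320DM;HCT116 p53-/-;HT29;LS411N;LoVo;NCI H508;NCI H716;SW837	Intron of FHIT
3p14.2	60659727	60699679	0.04	-0.3 to -2.2	Colo201;Colo320DM;HCT116 p53-/-;HT29;LS411N;NCI H716;SW837	Intron of FHIT
5q13.2	68918436	69002998	0.08	-0.4 to -0.7	Colo201;LS411N;LoVo;SK-CO-1;SW480;SW837;T84	SMA4;GTF2H2B;GTF2H2C;GTF2H2D;GTF2H2;GUSBP3;LOC100272216
5q13.2	69002998	69127115	0.1	-0.4 to -0.7	Colo201;Colo320DM;HT29;LS411N;LoVo;SK-CO-1;SW480;SW837;T84	contained within SMA4
5q13.2	69127115	69684303	0.6	-0.4 to -0.7	Colo201;Colo320DM;HT29;LS411N;LoVo;SK-CO-1;SW48;SW480;SW837;T84	
5q13.2	69684303	70543264	0.9	-0.4 to -0.7	Colo201;Colo320DM;HT29;LS411N;LoVo;SK-CO-1;SW480;SW837;T84	SMA4;GTF2H2B;GTF2H2C;GTF2H2D;SMA5;LOC441081;GUSBP9;SERF1A;SERF1B;SMN2;SMN1;NAIP;LOC647859
5q13.2	70543264	70669127	0.1	-0.4 to -0.7	Colo201;Colo320DM;HT29;LS411N;LoVo;SK-CO-1;SW480;SW837	GUSBP9
8p23.1	6759882	6779798	0.02	-0.3 to -1.4	HT29;NCI H508;NCI H716;SK-CO-1;SW480;SW837;T84	DEFA6
8p23.1	6779798	6824457	0.04	-0.5 to -1.4	Colo320DM;HT29;LS411N;NCI H508;NCI H716;SK-CO-1;SW480;SW837;T84	DEFA10P;DEFA4
8p23.1	6824457	7196061	0.4	-0.5 to -1.4	Colo201;Colo320DM;HT29;LS411N;NCI H508;NCI H716;SK-CO-1;SW480;SW837;T84	
8p23.1	7196061	7243352	0.05	-0.5 to -1.2	Colo201;Colo320DM;HT29;LS411N;NCI H716;SK-CO-1;SW480;SW837;T84	ZNF705G
8p23.1	7243352	7760349	0.5	-0.5 to -1.2	Colo201;Colo320DM;HT29;LS411N;NCI H716;SK-CO-1;SW48;SW480;SW837;T84	
8p23.1	7760349	7767962	0.01	-0.5 to -1.2	Colo201;Colo320DM;HT29;LS411N;NCI H716;SK-CO-1;SW480;SW837;T84	
8p23.1	7767962	8024923	0.3	-0.4 to -1.2	Colo201;Colo320DM;HT29;NCI H716;SK-CO-1;SW480;SW837;T84	DEFB103A;DEFB103B;DEFB109P1B;DEFB4A;FAM66E;MIR548I3;USP17L3;USP17L8;ZNF705B
8p23.1	11368117	11512387	0.1	-0.3 to -1.0	HT29;LS411N;NCI H716;SK-CO-1;SW480;SW837;T84	BLK;LINC00208
8p22	15174627	15414385	0.2	-0.3 to -0.8	HT29;NCI H508;NCI H716;SK-CO-1;SW480;SW837;T84	
9p12	41613166	41759552	0.1	-0.4 to -1.1	HCT116;HT29;LoVo;NCI H508;NCI H716;SW48;T84	
9p12-11.2	41759552	43003659	1.2	-0.4 to -1.1	Colo320DM;HCT116;HT29;LoVo;NCI H508;NCI H716;SW48;T84	MGC21881;KGFLP2;LOC643648;ANKRD20A2;ANKRD20A3;FAM95B1;FOXD4L4;FOXD4L2;LOC286297;AQP7P3
9p11.2	43003659	43678360	0.7	-0.4 to -1.1	Colo320DM;HT29;LoVo;NCI H508;NCI H716;SW48;T84	ANKRD20A2;ANKRD20A3;FAM95B1;LOC642929;FAM75A6;CNTNAP3B
9p11.2-q13	43794421	70017489	26.2	-0.4 to -1.1	Colo320DM;HT29;LoVo;NCI H508;NCI H716;SW48;T84	CNTNAP3B;LOC643648;FAM27C;FAM27A;KGFLP1
14q11.1-q11.2	18407780	19456314	1.0	-0.3 to -1.4	HT29;LS411N;LoVo;NCI H508;NCI H716;SW48;SW480;SW837;T84	LOC642426;OR11H12;OR11H2;OR4K2;OR4M1;OR4N2;OR4Q3;POTEG;POTEM
18q21.1	43485291	44789986	1.3	-0.3 to -0.9	Colo201;DLD-1;LS411N;NCI H716;SW480;SW837;T84	CTIF;MIR4743;SMAD2;SMAD7;ZBTB7C
18q21.1	45939166	46237377	0.3	-0.4 to -0.9	Colo201;LS411N;NCI H508;NCI H716;SW480;SW837;T84	CCDC11;CXXC1;MBD1;SKA1
18q21.2	47301645	49512571	2.2	-0.4 to -0.9	Colo201;LS411N;NCI H716;SK-CO-1;SW480;SW837;T84	DCC
18q21.2-q23	51105332	76108541	25.0	-0.4 to -1.1	Colo201;LS411N;NCI H716;SK-CO-1;SW480;SW837;T84	TCF4;TXNL1;WDR7;ONECUT2;FECH;NARS;ATP8B1;NEDD4L;MALT1;ZNF532;SEC11C;GRP;RAX;LMAN1;CCBE1;PMAIP1;MC4R;CDH20;RNF152;PIGN;TNFRSF11A;ZCCHC2;PHLPP2;BCL2;KDSR;VPS4B;SERPINB5;CDH7;CDH19;DSEL;TMX3;CCDC102B;DOK6;CD226;RTTN;SOCS6;CBLN2;NETO1;CYB5A;CNDP2;CNDP1;ZNF407;ZADH2;TSHZ1;ZNF516;ZNF236;MBP;GALR1;SALL3;ATP9B;NFATC1;CTDP1;KCNG2;PQLC1;TXNL4A;RBFA;ADNP2;PARD6G
20p12.1	14636068	14938351	0.3	-0.4 to -3.2	Colo201;HT29;NCI H508;NCI H716;SW480;SW837;T84	MACROD2
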