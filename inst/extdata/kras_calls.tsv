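sample	cds_pos	ref	alt	label_printed
DLD-1	38	G	A	G13D
HCT116	38	G	A	G13D
HCT116 p53-/-	38	G	A	G13D
LoVo	38	G	A	G13D
SK-CO-1	35	G	T	G12V
SW480	35	G	T	G12V
SW837	34	G	T	G12C
T84	38	G	A	G13D
Colo201	NA	NA	NA	WT
Colo320DM	NA	NA	NA	WT
HT29	NA	NA	NA	WT
LS411N	NA	NA	NA	WT
NCI H508	NA	NA	NA	WT
NCI H716	NA	NA	NA	WT
SW48	NA	NA	NA	WT
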