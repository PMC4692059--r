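file	md5
table1_gains.tsv	101015ffa56773ab022ad2c0ba698d7d
table2_losses.tsv	2b38472d0f38b6ec8be13a6f6cad4e07
drug_gene_lists.tsv	c321218278cb648e708d394c993c879d
kras_calls.tsv	8852f77bdcb742e8a63444a3b837f7d7
kras_cds_5prime.txt	012f80be93ad27600d99d2102709c3d8
gene_aliases.tsv	d98958744e02859a72a2276be29689d4
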