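# KRAS coding sequence, 5' fragment (first 30 codons, 90 bp), read in frame
# from the ATG.  Covers the exon-2 hotspot codons 12 (c.34-36, GGT) and
# 13 (c.37-39, GGC).
ATGACTGAATATAAACTTGTGGTAGTTGGAGCTGGTGGCGTAGGCAAGAGTGCCTTGACGATACAGCTAATTCAGAATCATTTTGTGGAC
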