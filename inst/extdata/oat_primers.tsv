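gene	forward	reverse	amplicon_bp	n_copies	efficiency_percent
PP2A	GCCCTGAGCCTACAAGAACGG	GCTGAGCGAACATGCTGAGAT	196	1	100.4
UBQ10	GATCTCAGCTCTAGCGAATCTCC	ATCCCTTCCTTGTCTTGAATCTTG	136	1	94.2
EF1A	GTGAAGATGATTCCCACCAAGC	CCTCATGTCACGCACAGCAAA	87	1	96.0
HNR	ATTGGGTTTGTCACTTTCCGTAG	CTTGGAGGGTGTCTCGCATCT	134	1	101.5
EP	GCACAAGTGATGCCAGAATAGC	CGAGATGCATTAGATTCGTTGG	193	1	112.4
TBC	TCCTCTTTCACCTCCCGATTAC	CAGATGCTTGCCCTTCTACCTC	98	1	92.7
EIF4A	TCTCGCAGGATACGGATGTCG	TCCATCGCATTGGTCGCTCT	88	1	100.8
18S	TTCTTAGTTGGTGGAGCGATTT	CCTGTTATTGCCTCAAACTTCC	150	2	100.4
GAPDH1	CTTCAACATCATTCCCAGCAG	GCCTTGGCGTCAAAGATGCT	288	2	110.7
TUA6	CCCAACAATGTGAAGTCCAGC	TGAACTGCTCACTCACCCTCC	121	3	NA
UBC21	GCCCATCGGAGACACCTTTTG	CCTGTCTTGAAGTGAACATTTGG	133	4	97.8
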