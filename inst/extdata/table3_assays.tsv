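name	target	type	forward	reverse	probe	length
SC-1	SC	cPCR	GGACCCAGTACTATTAACTGCTCTA	TCCTAGGGCAAGGAGGGTA		171
SC-5	SC	cPCR	TCCGATTACCGCCACAATTATAGCCTTAG	GATAGGGTTAGTGGAAGAGAGGAC		161
SC-7	SC	cPCR	ACTGAATAAACACACACATGTTCGAT	ATCATCACCCGATTAGTAAAAATG		275
SC-TM4	SC	qPCR	CCACTAACATCACCACGCAA	AGCCTTTTCCAGAGGCTTGG	TAACCCAGCTGCCAATACAA	168
SC-TM5	SC	qPCR	CCACAACTTACCCTCCTTGCC	AAGGGTATTAATTTTTGTGGTGGA	TCATGACATCCGCAGCATTCCTC	98
BH-6	BHC	cPCR	CAATACCCTAGCAATTATTCCCTTA	TGTAATTCCAAGGGCGGTTAG		375
BH-8	BHC	cPCR	gatgtaaactatggctggcttatt	tgtagaaagaggaggtgtaggaa		388
BH-TM1	BHC	qPCR	TAGACCTTCTAACAGGACTAATTC	AATCCACCTCATCCTCCAAC	CCGCCCTTGGAATTACATCCACA	144
BH-TM2	BHC	qPCR	CCTTCGTCAAACAGACCTTAAATCC	CCCTCATGGGGTTTGGATTAGA	CCACATAGGACTTGTAGCGGGTGGA	96
BH-TM4	BHC	qPCR	CCACTAACATCGCCACGTAG	AACCTTTTCCAGAAGCTTGG	TAGCCCAGCCGCCAACACAA	168
AC-6	SC+BHC	cPCR	GTTCCTAATCAGCACCTTAGTACTCT	AATTCGAAGGGATGGCAAG		156
AC-TM1	SC+BHC	qPCR	GGCCGGAACAGGATGAACAGTT	TAATAGTTGTGGTGATGAAGTTAATTG	CACGCAGGAGCATCCGTAGACCT	145
AC-TM2	SC+BHC	qPCR	CAATTAACTTCATCACCACAACTATTA	TCCAGCAGCTAAAACTGGTAAGG	AAACACCTCTCTTTGTTTGAGCTGTGC	133
AC-TM3	SC+BHC	qPCR	TTCATCGGCGTAAATCTTACAT	AGGGAAATAAGAGATCCGATAGA	ACCCAGATGCCTACGCCCTG	133
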