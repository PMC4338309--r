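name	target	type	forward	reverse	probe	length
QAPP-SC	SC	cPCR	CCTGARAAAAGARKTRTTCCACTATAA	GCCAAATGCAAGTAATAGTTCATTC		
QAPP-BH	BHC	cPCR	TAACTTAAATAAACAGATTA	TAAAAGAATGCTCGGCATGT		
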