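marker,target,type,steele_bayou_positives,steele_bayou_n,fishing_creek_positives,fishing_creek_n
QAPP-SC,SC,cPCR,28,44,0,44
SC-1,SC,cPCR,32,44,0,44
SC-5,SC,cPCR,25,44,0,44
SC-7,SC,cPCR,23,44,0,44
SC-TM4,SC,qPCR,26,44,0,44
SC-TM5,SC,qPCR,32,44,0,44
QAPP-BH,BHC,cPCR,0,44,,
BH-6,BHC,cPCR,6,44,0,44
BH-8,BHC,cPCR,6,44,0,44
BH-TM1,BHC,qPCR,9,44,0,44
BH-TM2,BHC,qPCR,7,44,0,44
BH-TM4,BHC,qPCR,6,44,0,44
AC-6,SC+BHC,cPCR,30,44,0,44
AC-TM1,SC+BHC,qPCR,25,44,0,44
AC-TM2,SC+BHC,qPCR,30,44,0,44
AC-TM3,SC+BHC,qPCR,28,42,0,44
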