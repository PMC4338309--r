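marker,target,type,dilution,proportion
QAPP-SC,SC,cPCR,10^-1,1.00
QAPP-SC,SC,cPCR,10^-2,1.00
QAPP-SC,SC,cPCR,10^-3,1.00
QAPP-SC,SC,cPCR,10^-4,1.00
QAPP-SC,SC,cPCR,10^-5,0
QAPP-SC,SC,cPCR,10^-6,0
QAPP-SC,SC,cPCR,10^-7,0
SC-1,SC,cPCR,10^-1,1.00
SC-1,SC,cPCR,10^-2,1.00
SC-1,SC,cPCR,10^-3,1.00
SC-1,SC,cPCR,10^-4,0.75
SC-1,SC,cPCR,10^-5,0
SC-1,SC,cPCR,10^-6,0
SC-1,SC,cPCR,10^-7,0
SC-5,SC,cPCR,10^-1,1.00
SC-5,SC,cPCR,10^-2,1.00
SC-5,SC,cPCR,10^-3,1.00
SC-5,SC,cPCR,10^-4,1.00
SC-5,SC,cPCR,10^-5,0
SC-5,SC,cPCR,10^-6,0.50
SC-5,SC,cPCR,10^-7,0
SC-7,SC,cPCR,10^-1,1.00
SC-7,SC,cPCR,10^-2,1.00
SC-7,SC,cPCR,10^-3,1.00
SC-7,SC,cPCR,10^-4,1.00
SC-7,SC,cPCR,10^-5,0
SC-7,SC,cPCR,10^-6,0
SC-7,SC,cPCR,10^-7,0
SC-TM4,SC,qPCR,10^-1,1.00
SC-TM4,SC,qPCR,10^-2,1.00
SC-TM4,SC,qPCR,10^-3,1.00
SC-TM4,SC,qPCR,10^-4,1.00
SC-TM4,SC,qPCR,10^-5,0.25
SC-TM4,SC,qPCR,10^-6,0.25
SC-TM4,SC,qPCR,10^-7,0
SC-TM5,SC,qPCR,10^-1,1.00
SC-TM5,SC,qPCR,10^-2,1.00
SC-TM5,SC,qPCR,10^-3,1.00
SC-TM5,SC,qPCR,10^-4,0.75
SC-TM5,SC,qPCR,10^-5,0.50
SC-TM5,SC,qPCR,10^-6,0.25
SC-TM5,SC,qPCR,10^-7,0.25
QAPP-BH,BHC,cPCR,10^-1,1.00
QAPP-BH,BHC,cPCR,10^-2,1.00
QAPP-BH,BHC,cPCR,10^-3,1.00
QAPP-BH,BHC,cPCR,10^-4,1.00
QAPP-BH,BHC,cPCR,10^-5,0.25
QAPP-BH,BHC,cPCR,10^-6,0.25
QAPP-BH,BHC,cPCR,10^-7,0
BH-6,BHC,cPCR,10^-1,1.00
BH-6,BHC,cPCR,10^-2,1.00
BH-6,BHC,cPCR,10^-3,1.00
BH-6,BHC,cPCR,10^-4,0.25
BH-6,BHC,cPCR,10^-5,0
BH-6,BHC,cPCR,10^-6,0
BH-6,BHC,cPCR,10^-7,0
BH-8,BHC,cPCR,10^-1,1.00
BH-8,BHC,cPCR,10^-2,1.00
BH-8,BHC,cPCR,10^-3,1.00
BH-8,BHC,cPCR,10^-4,0.75
BH-8,BHC,cPCR,10^-5,0
BH-8,BHC,cPCR,10^-6,0.25
BH-8,BHC,cPCR,10^-7,0
BH-TM1,BHC,qPCR,10^-1,1.00
BH-TM1,BHC,qPCR,10^-2,1.00
BH-TM1,BHC,qPCR,10^-3,1.00
BH-TM1,BHC,qPCR,10^-4,0.75
BH-TM1,BHC,qPCR,10^-5,0.25
BH-TM1,BHC,qPCR,10^-6,0
BH-TM1,BHC,qPCR,10^-7,0
BH-TM2,BHC,qPCR,10^-1,1.00
BH-TM2,BHC,qPCR,10^-2,1.00
BH-TM2,BHC,qPCR,10^-3,1.00
BH-TM2,BHC,qPCR,10^-4,0.75
BH-TM2,BHC,qPCR,10^-5,0
BH-TM2,BHC,qPCR,10^-6,0
BH-TM2,BHC,qPCR,10^-7,0
BH-TM4,BHC,qPCR,10^-1,1.00
BH-TM4,BHC,qPCR,10^-2,1.00
BH-TM4,BHC,qPCR,10^-3,1.00
BH-TM4,BHC,qPCR,10^-4,0.75
BH-TM4,BHC,qPCR,10^-5,0
BH-TM4,BHC,qPCR,10^-6,0.25
BH-TM4,BHC,qPCR,10^-7,0
AC-6,SC+BHC,cPCR,10^-1,1.00
AC-6,SC+BHC,cPCR,10^-2,1.00
AC-6,SC+BHC,cPCR,10^-3,1.00
AC-6,SC+BHC,cPCR,10^-4,0.50
AC-6,SC+BHC,cPCR,10^-5,0
AC-6,SC+BHC,cPCR,10^-6,0.25
AC-6,SC+BHC,cPCR,10^-7,0
AC-TM1,SC+BHC,qPCR,10^-1,1.00
AC-TM1,SC+BHC,qPCR,10^-2,1.00
AC-TM1,SC+BHC,qPCR,10^-3,1.00
AC-TM1,SC+BHC,qPCR,10^-4,0.50
AC-TM1,SC+BHC,qPCR,10^-5,0.50
AC-TM1,SC+BHC,qPCR,10^-6,0
AC-TM1,SC+BHC,qPCR,10^-7,0
AC-TM2,SC+BHC,qPCR,10^-1,1.00
AC-TM2,SC+BHC,qPCR,10^-2,1.00
AC-TM2,SC+BHC,qPCR,10^-3,1.00
AC-TM2,SC+BHC,qPCR,10^-4,1.00
AC-TM2,SC+BHC,qPCR,10^-5,0.50
AC-TM2,SC+BHC,qPCR,10^-6,0
AC-TM2,SC+BHC,qPCR,10^-7,0
AC-TM3,SC+BHC,qPCR,10^-1,1.00
AC-TM3,SC+BHC,qPCR,10^-2,1.00
AC-TM3,SC+BHC,qPCR,10^-3,1.00
AC-TM3,SC+BHC,qPCR,10^-4,0.75
AC-TM3,SC+BHC,qPCR,10^-5,0
AC-TM3,SC+BHC,qPCR,10^-6,0
AC-TM3,SC+BHC,qPCR,10^-7,0
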