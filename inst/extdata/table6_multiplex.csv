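species,trial,marker,dilution,cq,copies_low,copies_high
SC,single,SC-TM4,10^-2,30.6,195,424
SC,single,SC-TM4,10^-3,34.1,10,50
SC,single,SC-TM4,10^-4,37.3,0,12
SC,single,SC-TM4,10^-5,38.7,0,2.4
SC,single,SC-TM5,10^-2,30.4,872,1498
SC,single,SC-TM5,10^-3,33.7,60,208
SC,single,SC-TM5,10^-4,37.4,0,30
SC,single,SC-TM5,10^-5,38.1,0,11
SC,multiplex,SC-TM4,10^-2,30.7,203,422
SC,multiplex,SC-TM4,10^-3,34.2,11,50
SC,multiplex,SC-TM4,10^-4,37.9,0,5
SC,multiplex,SC-TM4,10^-5,38.4,0,3
SC,multiplex,SC-TM5,10^-2,30.4,1145,1792
SC,multiplex,SC-TM5,10^-3,33.9,81,200
SC,multiplex,SC-TM5,10^-4,37.5,2,23
SC,multiplex,SC-TM5,10^-5,38.4,0,14
BHC,single,BH-TM1,10^-2,31.2,107,244
BHC,single,BH-TM1,10^-3,34.6,8,28
BHC,single,BH-TM1,10^-4,38.2,0,4
BHC,single,BH-TM1,10^-5,39.0,0,1
BHC,single,BH-TM2,10^-2,31.2,120,216
BHC,single,BH-TM2,10^-3,34.8,7,19
BHC,single,BH-TM2,10^-4,37.8,0,4
BHC,single,BH-TM2,10^-5,39.3,0,1
BHC,multiplex,BH-TM1,10^-2,30.6,118,263
BHC,multiplex,BH-TM1,10^-3,34.3,8,23
BHC,multiplex,BH-TM1,10^-4,37.3,0,5
BHC,multiplex,BH-TM1,10^-5,38.3,0,1
BHC,multiplex,BH-TM2,10^-2,31.1,137,201
BHC,multiplex,BH-TM2,10^-3,34.6,12,24
BHC,multiplex,BH-TM2,10^-4,38.1,0,7
BHC,multiplex,BH-TM2,10^-5,38.7,0,1
SC+BHC,single,AC-TM1,10^-2,31.1,241,358
SC+BHC,single,AC-TM1,10^-3,34.5,16,65
SC+BHC,single,AC-TM1,10^-4,38.0,0,12
SC+BHC,single,AC-TM1,10^-5,38.9,0,3
SC+BHC,single,AC-TM3,10^-2,29.1,225,398
SC+BHC,single,AC-TM3,10^-3,32.3,16,52
SC+BHC,single,AC-TM3,10^-4,36.0,0,6
SC+BHC,single,AC-TM3,10^-5,37.7,0,1
SC+BHC,multiplex,AC-TM1,10^-2,31.1,283,536
SC+BHC,multiplex,AC-TM1,10^-3,34.5,22,91
SC+BHC,multiplex,AC-TM1,10^-4,37.7,0,16
SC+BHC,multiplex,AC-TM1,10^-5,39.4,0,1
SC+BHC,multiplex,AC-TM3,10^-2,29.1,252,501
SC+BHC,multiplex,AC-TM3,10^-3,32.4,19,80
SC+BHC,multiplex,AC-TM3,10^-4,35.9,0,12
SC+BHC,multiplex,AC-TM3,10^-5,37.6,0,2
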