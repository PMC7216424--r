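patient_id,age,gender,etiology,months_since_injury,diagnosis,crs_r_sum,excluded
P1,43,M,NTBI,39.0,EMCS,11,FALSE
P2,72,F,NTBI,10.0,UWS,6,FALSE
P3,25,M,NTBI,99.0,UWS,6,FALSE
P4,34,M,TBI,15.0,UWS,6,FALSE
P5,60,M,NTBI,7.0,UWS,7,FALSE
P6,49,F,NTBI,16.0,UWS,6,FALSE
P7,50,M,NTBI,4.0,UWS,3,FALSE
P8,59,F,NTBI,6.0,UWS,6,FALSE
P9,60,M,NTBI,7.0,UWS,7,FALSE
P10,68,M,NTBI,5.0,UWS,6,FALSE
P11,70,F,TBI,7.0,UWS,3,FALSE
P12,48,F,NTBI,37.0,UWS,5,FALSE
P13,66,M,NTBI,2.0,UWS,7,FALSE
P14,20,M,TBI,56.0,MCS,13,FALSE
P15,71,M,NTBI,24.0,UWS,1,FALSE
P16,55,F,TBI,168.0,MCS,17,FALSE
P17,70,F,NTBI,15.0,UWS,3,FALSE
P18,51,M,TBI,54.0,UWS,4,FALSE
P19,61,F,NTBI,9.0,EMCS,23,FALSE
P20,68,M,NTBI,415.0,UWS,4,FALSE
P21,53,F,NTBI,10.5,MCS,13,FALSE
P22,68,F,TBI,13.5,MCS,9,FALSE
P23,71,F,TBI,2.5,EMCS,23,FALSE
P24,53,F,NTBI,82.0,UWS,5,FALSE
P25,37,M,TBI,197.0,MCS,9,FALSE
P26,46,F,NTBI,3.0,UWS,4,TRUE
P27,19,F,TBI,17.0,MCS,8,FALSE
P28,78,M,NTBI,13.0,MCS,9,FALSE
P29,27,M,NTBI,1.5,UWS,4,FALSE
P30,54,M,TBI,10.0,EMCS,20,FALSE
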