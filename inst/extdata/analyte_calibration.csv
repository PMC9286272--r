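analyte,label,units,decimals,partition,q_low,q_med,q_high
WBC,WBC,10^9/L,1,T1,3.6,7.7,13.2
WBC,WBC,10^9/L,1,T2,4.56,8.2,13.59
WBC,WBC,10^9/L,1,T3,4.56,8.6,13.62
WBC,WBC,10^9/L,1,NP,3.6,6.5,10.3
Lymph_abs,Lymph#,10^9/L,2,T1,1.1,2.0,2.8
Lymph_abs,Lymph#,10^9/L,2,T2,1.03,1.8,2.6
Lymph_abs,Lymph#,10^9/L,2,T3,1.13,1.9,2.77
Lymph_abs,Lymph#,10^9/L,2,NP,1.24,2.3,3.7
MID_abs,MID#,10^9/L,2,T1,0.2,0.5,0.9
MID_abs,MID#,10^9/L,2,T2,0.2,0.5,1.08
MID_abs,MID#,10^9/L,2,T3,0.2,0.5,1.08
MID_abs,MID#,10^9/L,2,NP,0.2,0.4,0.8
Gran_abs,Gran#,10^9/L,2,T1,2.23,5.3,8.62
Gran_abs,Gran#,10^9/L,2,T2,2.42,5.9,9.78
Gran_abs,Gran#,10^9/L,2,T3,2.61,6.2,10.23
Gran_abs,Gran#,10^9/L,2,NP,1.3,3.5,6.9
Lymph_pct,Lymph%,%,1,T1,12.78,24.9,45.60
Lymph_pct,Lymph%,%,1,T2,10.96,20.8,32.96
Lymph_pct,Lymph%,%,1,T3,13.53,22.2,45.68
Lymph_pct,Lymph%,%,1,NP,19.9,35.7,57.1
MID_pct,MID%,%,1,T1,3.94,6.8,12.00
MID_pct,MID%,%,1,T2,3.74,6.65,9.60
MID_pct,MID%,%,1,T3,3.83,6.8,12.33
MID_pct,MID%,%,1,NP,3.9,6.8,10.9
Gran_pct,Gran%,%,1,T1,45.86,65.8,80.42
Gran_pct,Gran%,%,1,T2,58.62,70.4,81.50
Gran_pct,Gran%,%,1,T3,60.53,71.9,82.55
Gran_pct,Gran%,%,1,NP,33.4,56.1,71.8
Hgb,Hgb,g/dL,1,T1,10.37,12.3,13.53
Hgb,Hgb,g/dL,1,T2,9.99,11.6,12.90
Hgb,Hgb,g/dL,1,T3,10.68,12.7,13.71
Hgb,Hgb,g/dL,1,NP,12.4,13.1,14.3
RBC,RBC,10^12/L,2,T1,3.58,3.86,4.90
RBC,RBC,10^12/L,2,T2,3.35,3.49,4.01
RBC,RBC,10^12/L,2,T3,3.76,3.78,4.99
RBC,RBC,10^12/L,2,NP,4.44,4.76,5.01
HCT,HCT,%,1,T1,34.86,41.05,47.80
HCT,HCT,%,1,T2,33.93,40.3,46.19
HCT,HCT,%,1,T3,32.33,39.9,45.98
HCT,HCT,%,1,NP,38.4,44.6,50.1
MCV,MCV,fL,1,T1,86.67,94.2,103.03
MCV,MCV,fL,1,T2,86.10,94.4,103.58
MCV,MCV,fL,1,T3,87.62,95.0,105.77
MCV,MCV,fL,1,NP,86.1,92.6,101.6
MCH,MCH,pg,1,T1,26.40,30.0,32.94
MCH,MCH,pg,1,T2,26.89,30.1,33.20
MCH,MCH,pg,1,T3,27.51,30.4,33.99
MCH,MCH,pg,1,NP,27.1,29.8,32.4
MCHC,MCHC,g/dL,1,T1,30.30,32.5,33.66
MCHC,MCHC,g/dL,1,T2,30.13,31.9,33.2
MCHC,MCHC,g/dL,1,T3,30.31,32.6,33.86
MCHC,MCHC,g/dL,1,NP,30.4,31.9,34.1
RDW_CV,RDW-CV,%,1,T1,12.44,14.1,15.99
RDW_CV,RDW-CV,%,1,T2,12.52,14.2,17.00
RDW_CV,RDW-CV,%,1,T3,12.62,13.9,16.20
RDW_CV,RDW-CV,%,1,NP,12.1,12.4,14.7
RDW_SD,RDW-SD,fL,1,T1,40.60,46.5,55.50
RDW_SD,RDW-SD,fL,1,T2,42.28,49.6,57.99
RDW_SD,RDW-SD,fL,1,T3,41.30,49.2,59.84
RDW_SD,RDW-SD,fL,1,NP,39.7,45.4,57.3
PLT,Platelet,10^9/L,0,T1,167.05,273,390.00
PLT,Platelet,10^9/L,0,T2,149.58,253,373.32
PLT,Platelet,10^9/L,0,T3,124.60,245,356.90
PLT,Platelet,10^9/L,0,NP,173,304,456
MPV,MPV,fL,1,T1,6.73,8.6,9.80
MPV,MPV,fL,1,T2,7.05,8.78,10.25
MPV,MPV,fL,1,T3,7.40,8.85,10.30
MPV,MPV,fL,1,NP,7.1,8.5,10.1
PDW,PDW,index,1,T1,15.10,15.7,16.36
PDW,PDW,index,1,T2,15.22,15.8,16.48
PDW,PDW,index,1,T3,15.16,15.9,16.57
PDW,PDW,index,1,NP,14.1,14.5,15.5
PCT,PCT,%,3,T1,0.152,0.22,0.316
PCT,PCT,%,3,T2,0.110,0.217,0.321
PCT,PCT,%,3,T3,0.118,0.21,0.321
PCT,PCT,%,3,NP,0.168,0.267,0.382
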