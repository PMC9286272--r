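analyte,group,n,mean,median,q_low,q_high
WBC,Pregnant,395,8.3,8.1,4.0,13.2
Lymph_abs,Pregnant,395,1.9,1.9,1.1,2.71
MID_abs,Pregnant,393,0.6,0.5,0.2,1.0
Gran_abs,Pregnant,393,5.8,5.8,2.2,9.8
Lymph_pct,Pregnant,384,23.4,22.5,12.9,38.1
MID_pct,Pregnant,390,7.6,7.4,4.2,11.6
Gran_pct,Pregnant,390,69.3,70.4,50.5,81.5
Hgb,Pregnant,394,10.9,11.9,10.1,13.7
RBC,Pregnant,396,3.5,3.52,3.45,4.67
HCT,Pregnant,396,40.2,40.4,33.5,46.5
MCV,Pregnant,391,94.7,94.7,84.8,103.5
MCH,Pregnant,370,30.3,30.2,27.5,33.0
MCHC,Pregnant,389,31.9,31.9,30.3,33.7
RDW_CV,Pregnant,381,14.9,14.7,12.5,16.1
RDW_SD,Pregnant,389,49.0,48.3,42.1,58.2
PLT,Pregnant,393,256,253,132,373
MPV,Pregnant,395,8.8,8.7,7.2,10.2
PDW,Pregnant,393,15.8,15.8,15.2,16.4
PCT,Pregnant,384,0.216,0.217,0.121,0.316
WBC,NonPregnant,136,6.6,6.5,3.6,10.3
Lymph_abs,NonPregnant,136,2.3,2.3,1.24,3.7
MID_abs,NonPregnant,135,0.5,0.4,0.2,0.8
Gran_abs,NonPregnant,135,3.7,3.5,1.3,6.9
Lymph_pct,NonPregnant,134,36.6,35.7,19.9,57.1
MID_pct,NonPregnant,135,6.9,6.8,3.9,10.9
Gran_pct,NonPregnant,135,55.5,56.1,33.4,71.8
Hgb,NonPregnant,135,13.8,13.1,12.4,14.3
RBC,NonPregnant,134,4.7,4.76,4.44,5.01
HCT,NonPregnant,134,44.2,44.6,38.4,50.1
MCV,NonPregnant,135,92.3,92.6,86.1,101.6
MCH,NonPregnant,133,29.7,29.8,27.1,32.4
MCHC,NonPregnant,135,32.0,31.9,30.4,34.1
RDW_CV,NonPregnant,127,12.3,12.4,12.1,14.7
RDW_SD,NonPregnant,133,45.5,45.4,39.7,57.3
PLT,NonPregnant,136,310,304,173,456
MPV,NonPregnant,136,8.6,8.5,7.1,10.1
PDW,NonPregnant,133,14.5,14.0,14.1,15.5
PCT,NonPregnant,136,0.269,0.267,0.168,0.382
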