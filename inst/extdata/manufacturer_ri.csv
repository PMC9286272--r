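analyte,mfr_low,mfr_high,est_low,est_high,below_n,above_n
WBC,4.0,10.0,4.0,13.2,0,86
Lymph_abs,0.8,4.0,1.1,2.7,5,11
MID_abs,0.1,1.5,0.2,1.0,0,6
Gran_abs,2.0,7.0,2.2,9.8,3,104
Lymph_pct,20.0,40.0,12.9,38.1,120,5
MID_pct,3.0,15.0,3.9,10.9,6,10
Gran_pct,50.0,70.0,50.5,81.5,1,194
Hgb,11.0,15.0,10.1,13.7,22,97
RBC,3.50,5.00,3.45,4.67,3,56
HCT,37.0,47.0,33.5,46.5,53,3
MCV,80.0,100.0,84.8,103.5,9,40
MCH,27.0,34.0,27.5,33.0,4,8
MCHC,32.0,36.0,30.3,33.7,190,12
RDW_CV,11.0,16.0,12.5,16.1,7,0
RDW_SD,35.0,56.0,42.1,58.2,8,15
PLT,100,300,131.7,373.2,9,78
MPV,6.5,12.0,7.1,10.1,9,2
PDW,9.0,17.0,15.2,16.4,8,10
PCT,0.108,0.282,0.121,0.316,6,21
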