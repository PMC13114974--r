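descriptor,analyte,conc_mM,mean,sd,n,units
B_A1,propionate,0,714.68,2.11,3,uA.mV
B_A1,propionate,1,926.66,56.33,3,uA.mV
B_A1,propionate,2,1126.66,75.25,3,uA.mV
B_A1,propionate,3,1303.02,63.56,3,uA.mV
C_I1,butyrate,0,9.19,1.13,3,uA
C_I1,butyrate,1,11.32,0.25,3,uA
C_I1,butyrate,2,12.07,0.24,3,uA
C_I1,butyrate,3,13.24,0.27,3,uA
A_A1,total,0,201.35,0.23,3,uA.mV
A_A1,total,5,289.17,25.69,3,uA.mV
A_A1,total,10,376.94,37.87,3,uA.mV
A_A1,total,15,406.48,22.04,3,uA.mV
A_A1,total,20,452.62,19.86,3,uA.mV
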