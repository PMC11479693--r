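patient_id,arm,n_cycles,mii,two_pn,blastocysts,embryos_transferred,transfer_day,hcg_positive,outcomes
P2,ICSI,5,65,5,NA,3,D2;D3,1,LB
P3,ICSI,1,10,0,NA,0,,0,
P4,ICSI,2,10,1,NA,0,,0,
P7,ICSI,4,81,2,NA,1,D2,0,
P9,ICSI,3,18,0,NA,0,,0,
P15,ICSI,3,16,5,NA,5,D3,0,
P18,ICSI,5,62,16,NA,3,D3,1,M
P20,ICSI,2,16,3,NA,2,D3,0,
P21,ICSI,1,8,0,NA,0,,0,
P23,ICSI,4,26,3,NA,2,D3,1,LB
P26,ICSI,1,11,0,NA,0,,0,
P29,ICSI,1,15,2,NA,1,D3,0,
P32,ICSI,1,4,1,NA,0,,0,
P34,ICSI,2,25,0,NA,0,,0,
P35,ICSI,2,15,1,NA,0,,0,
P36,ICSI,2,21,4,NA,4,D3,1,M
P44,ICSI,3,35,7,NA,3,D3;D5,1,LB
P46,ICSI,3,46,4,NA,1,D3,0,
P54,ICSI,2,14,2,NA,1,D5,0,
P2,ICSI_AOA,1,20,8,NA,5,D3,1,LB
P3,ICSI_AOA,8,63,43,NA,15,D2;D3,1,ND
P4,ICSI_AOA,1,6,5,NA,1,D3,0,
P7,ICSI_AOA,1,15,12,6,2,,1,LB
P9,ICSI_AOA,2,13,4,0,0,,0,
P15,ICSI_AOA,3,7,2,2,1,,1,BP
P18,ICSI_AOA,1,13,8,5,2,,2,BP;LB
P20,ICSI_AOA,1,13,8,7,5,,2,LB;LB
P21,ICSI_AOA,1,17,13,5,1,,1,LB
P23,ICSI_AOA,2,16,10,8,3,,1,M
P26,ICSI_AOA,1,18,14,10,5,,1,BP
P29,ICSI_AOA,1,11,9,6,3,,2,LB;LB
P32,ICSI_AOA,5,25,13,11,6,,2,LB;LB
P34,ICSI_AOA,1,11,11,8,2,,2,LB;BP
P35,ICSI_AOA,2,31,14,7,2,,1,LB
P36,ICSI_AOA,1,7,7,5,1,,0,
P44,ICSI_AOA,1,9,6,5,1,,1,LB
P46,ICSI_AOA,1,19,5,3,2,,1,Ong
P54,ICSI_AOA,1,8,7,6,1,,1,Ong
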