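cell_id,n_records,richness_total,richness_threatened,richness_endemic,richness_sensitive,mean_T+D,mean_T+LH,mean_D+LH,mean_T+D+M,mean_T+D+Tr,mean_T+D+LH
A1,4,2,1,1,1,3,3,3,4,4.5,4.5
A2,2,2,1,1,0,1.5,1.5,2,2,2.5,2.5
A3,1,1,0,0,0,0,0,0,0,0,0
B1,2,1,1,1,0,3,3,4,4,5,5
B2,3,2,1,2,1,4,3.5,4.5,5,6,6
B3,0,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
C1,3,1,1,1,0,5,3,4,7,5,6
C2,1,1,0,0,0,0,0,0,0,0,0
C3,1,1,0,0,0,0,0,0,0,0,0
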