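cell_id,count_based,score_based,biodiversity
A1,TRUE,FALSE,TRUE
A2,TRUE,FALSE,TRUE
A3,FALSE,FALSE,FALSE
B1,TRUE,FALSE,TRUE
B2,TRUE,TRUE,TRUE
B3,NA,NA,NA
C1,TRUE,TRUE,TRUE
C2,FALSE,FALSE,TRUE
C3,FALSE,FALSE,FALSE
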