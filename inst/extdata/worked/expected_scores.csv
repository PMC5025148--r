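species_id,status,T,D,M,Tr,LH,T+D,T+LH,D+LH,T+D+M,T+D+Tr,T+D+LH
spA,CR,3,3,2,3,3,6,6,6,8,9,9
spB,LC,0,0,0,0,0,0,0,0,0,0,0
spC,VU,1,2,1,2,2,3,3,4,4,5,5
spD,LC,0,2,0,1,1,2,1,3,2,3,3
spE,EN,2,3,2,0,1,5,3,4,7,5,6
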