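region,n_cells
count_only,0
score_only,0
bio_only,1
count_score,0
count_bio,3
score_bio,0
all_three,2
total_flagged,6
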