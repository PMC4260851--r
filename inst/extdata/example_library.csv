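song_id,bpm,duration_s,grid_file
walk_a,100,120,
walk_b,110,120,
walk_c,115,120,walk_c.grid
walk_d,120,120,
walk_e,130,120,
run_a,150,120,
run_b,165,120,
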