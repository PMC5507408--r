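specimen_id,free_height_mm,af_exp_N,af_fe_12gpa_N,af_fe_4p6gpa_N,tot_bvtv_pct,voxel_size_um
S#1,12.9,2953,6881,2643,41.3,39.0
S#2,12.6,1060,1910,734,40.3,38.6
S#3,10.8,1122,5256,2019,32.7,38.6
S#4,13.3,3028,6999,2689,48.6,38.6
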