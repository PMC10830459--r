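Hylak_id,Grid_id,Lake_type,Lake_area,Vol_total,Depth_avg,Res_time,Wshd_area,Year
9001,12,1,14.5,43.5,3.0,180,950,
9002,27,1,2.3,11.5,5.0,420,1.2,
9003,101,2,88.0,880.0,10.0,650,12400,1968
9004,233,1,0.4,1.2,3.0,95,3.8,
9005,310,2,5.6,28.0,5.0,300,7600,1994
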