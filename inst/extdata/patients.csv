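patient,risk,v_pre_db,v_post_db,v_pre_seg,v_post_seg,f_regressive,f_blastema,f_epithelium,f_stroma
P1,low,143.99,10.62,126.25,10.58,0.98,0,1,0
P2,intermediate,536.73,89.49,526.99,70.72,0.70,0.20,0,0.80
P3,high,306.99,126.29,235.64,108.22,0.05,0.70,0.05,0.25
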