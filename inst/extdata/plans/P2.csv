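# dt_post_treat: 1
day,drug
4,ACT
4,VCR
11,VCR
18,ACT
18,VCR
25,VCR
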