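# dt_post_treat: 6
day,drug
4,ACT
4,VCR
12,VCR
19,ACT
19,VCR
26,VCR
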