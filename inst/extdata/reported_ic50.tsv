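design	ic50_mut_nM	ic50_wt_nM
M-1	25	130
M-2	13	103
M-7	7	83
MM(1-7)	8	261
2'-OMe-2	NA	25.5
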