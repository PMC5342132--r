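case,subsample_1e4,full_2e5
case1,0.747,1.037
case2,0.108,0.101
case3,0.047,0.024
case4,0.305,0.304
case5,0.013,0.012
case6,1.974,1.986
case7,0.956,0.965
case8,1.222,1.621
case9,1.640,2.230
case10,1.174,1.253
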