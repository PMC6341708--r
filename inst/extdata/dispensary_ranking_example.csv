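council,facility,qual_rank,score,n_indicators,avg_answers
1,A,1,76,147,1.79
1,B,2,83,125,1.64
2,C,3,66,163,1.85
3,D,4,79,127,1.49
3,E,5,57,136,1.36
2,F,6,52,152,1.51
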