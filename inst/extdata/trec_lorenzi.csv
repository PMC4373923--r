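age_lo,age_hi,mean_log10_trec,n_individuals
0,0,4.85,2
1,4,5.29,30
5,9,5.05,33
10,14,4.99,15
15,19,4.56,5
20,24,4.55,12
25,29,4.55,9
30,34,4.44,20
35,39,4.23,15
40,44,4.16,9
45,49,3.82,16
50,54,4.21,21
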