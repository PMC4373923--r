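age_lo,age_hi,mean_log10_trec,n_individuals
0,0,5.03,48
1,4,4.93,53
5,9,4.86,19
10,14,4.86,19
15,19,4.56,33
20,24,3.88,26
25,29,3.75,47
30,34,3.61,65
35,39,3.54,73
40,44,3.52,52
45,49,3.37,55
50,54,3.17,16
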