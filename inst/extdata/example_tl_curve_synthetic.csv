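"range_m","rl_db"
1,177.511
2,171.49
3,167.968
4,165.47
5,163.532
7,160.609
8,159.449
11,156.683
13,155.232
17,152.902
22,150.662
27,148.884
35,146.63
44,144.642
55,142.704
70,140.609
89,138.523
113,136.449
143,134.404
180,132.405
229,130.314
289,128.293
367,126.218
464,124.181
588,122.827
744,121.805
943,120.776
1194,119.751
1512,118.726
1914,117.702
2424,116.676
3000,115.75
3070,115.65
3888,114.624
4924,113.598
6236,112.572
7897,111.547
10000,110.521
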