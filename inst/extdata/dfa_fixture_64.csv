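"value"
0.923365
-1.08221
0.364359
-0.409942
-0.357474
0.995913
0.082441
-0.305184
-0.924244
1.566594
1.009426
-0.260284
-0.090926
1.658358
0.829528
-0.086609
-0.417987
0.33153
1.228508
0.283478
-0.024026
-1.583294
0.032957
0.843291
-1.177047
-0.204585
1.390381
-0.577101
-1.271262
0.737026
1.868792
-0.668868
0.386561
0.216319
-1.640511
1.002785
-1.011568
0.302521
0.356229
0.995696
-0.259961
0.506019
0.922611
0.387852
0.093802
-0.522981
-1.10719
0.028911
-1.406273
-0.940311
1.87249
-0.069523
0.723315
-0.584094
0.766735
0.905271
-1.045175
0.452141
-0.726202
0.626386
0.255143
-1.226689
0.947976
-1.238369
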