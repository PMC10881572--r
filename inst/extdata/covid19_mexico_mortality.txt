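# COVID-19 mortality rate, Mexico, 108 days (4 March - 20 July 2020)
8.826
6.105
10.383
7.267
13.220
6.015
10.855
6.122
10.685
10.035
5.242
7.630
14.604
7.903
6.327
9.391
14.962
4.730
3.215
16.498
11.665
9.284
12.878
6.656
3.440
5.854
8.813
10.043
7.260
5.985
4.424
4.344
5.143
9.935
7.840
9.550
6.968
6.370
3.537
3.286
10.158
8.108
6.697
7.151
6.560
2.988
3.336
6.814
8.325
7.854
8.551
3.228
3.499
3.751
7.486
6.625
6.140
4.909
4.661
1.867
2.838
5.392
12.042
8.696
6.412
3.395
1.815
3.327
5.406
6.182
4.949
4.089
3.359
2.070
3.298
5.317
5.442
4.557
4.292
2.500
6.535
4.648
4.697
5.459
4.120
3.922
3.219
1.402
2.438
3.257
3.632
3.233
3.027
2.352
1.205
2.077
3.778
3.218
2.926
2.601
2.065
1.041
1.800
3.029
2.058
2.326
2.506
1.923
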