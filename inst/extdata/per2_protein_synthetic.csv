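# period_h=23.4 label=PER2_protein_synthetic units=normalized
time_h,value
0.2,0.3126
0.4,0.3237
0.6,0.3341
0.8,0.3443
1,0.3551
1.2,0.3670
1.4,0.3808
1.6,0.3972
1.8,0.4167
2,0.4400
2.2,0.4676
2.4,0.4990
2.6,0.5335
2.8,0.5703
3,0.6087
3.2,0.6480
3.4,0.6875
3.6,0.7265
3.8,0.7642
4,0.8000
4.2,0.8332
4.4,0.8636
4.6,0.8912
4.8,0.9159
5,0.9377
5.2,0.9564
5.4,0.9721
5.6,0.9846
5.8,0.9939
6,1.0000
6.2,1.0028
6.4,1.0025
6.6,0.9993
6.8,0.9936
7,0.9856
7.2,0.9756
7.4,0.9637
7.6,0.9503
7.8,0.9357
8,0.9200
8.2,0.9035
8.4,0.8864
8.6,0.8688
8.8,0.8507
9,0.8323
9.2,0.8138
9.4,0.7951
9.6,0.7766
9.8,0.7581
10,0.7400
10.2,0.7222
10.4,0.7049
10.6,0.6879
10.8,0.6713
11,0.6551
11.2,0.6393
11.4,0.6239
11.6,0.6089
11.8,0.5943
12,0.5800
12.2,0.5661
12.4,0.5526
12.6,0.5393
12.8,0.5263
13,0.5134
13.2,0.5007
13.4,0.4880
13.6,0.4754
13.8,0.4627
14,0.4500
14.2,0.4371
14.4,0.4240
14.6,0.4106
14.8,0.3968
15,0.3825
15.2,0.3675
15.4,0.3519
15.6,0.3355
15.8,0.3182
16,0.3000
16.2,0.2808
16.4,0.2609
16.6,0.2408
16.8,0.2208
17,0.2015
17.2,0.1831
17.4,0.1662
17.6,0.1511
17.8,0.1382
18,0.1280
18.2,0.1207
18.4,0.1161
18.6,0.1139
18.8,0.1136
19,0.1150
19.2,0.1175
19.4,0.1210
19.6,0.1250
19.8,0.1291
20,0.1330
20.2,0.1364
20.4,0.1396
20.6,0.1428
20.8,0.1462
21,0.1503
21.2,0.1553
21.4,0.1614
21.6,0.1691
21.8,0.1785
22,0.1900
22.2,0.2037
22.4,0.2192
22.6,0.2357
22.8,0.2527
23,0.2695
23.2,0.2855
23.4,0.3000
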