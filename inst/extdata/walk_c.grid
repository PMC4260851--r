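0.480
1.002
1.525
2.048
2.572
3.096
3.620
4.145
4.670
5.196
5.721
6.247
6.773
7.298
7.824
8.350
8.875
9.400
9.925
10.449
10.974
11.497
12.021
12.543
13.066
13.587
14.109
14.630
15.150
15.670
16.189
16.708
17.227
17.745
18.264
18.782
19.299
19.817
20.335
20.853
21.371
21.889
22.407
22.926
23.444
23.964
24.483
25.004
25.524
26.045
26.567
27.089
27.612
28.135
28.658
29.182
29.707
30.231
30.756
31.282
31.807
32.333
32.858
33.384
33.910
34.435
34.961
35.486
36.011
36.536
37.060
37.584
38.107
38.630
39.152
39.674
40.196
40.717
41.237
41.757
42.277
42.796
43.315
43.833
44.351
44.869
45.387
45.905
46.423
46.941
47.459
47.977
48.495
49.013
49.532
50.051
50.571
51.091
51.611
52.132
52.654
53.176
53.698
54.221
54.745
55.269
55.793
56.317
56.842
57.368
57.893
58.419
58.944
59.470
59.996
60.521
61.047
61.572
62.097
62.622
63.146
63.670
64.194
64.717
65.239
65.761
66.283
66.804
67.325
67.845
68.364
68.884
69.403
69.921
70.439
70.957
71.475
71.993
72.511
73.029
73.546
74.064
74.583
75.101
75.620
76.139
76.658
77.178
77.699
78.219
78.741
79.263
79.785
80.308
80.831
81.355
81.879
82.404
82.928
83.454
83.979
84.505
85.030
85.556
86.082
86.607
87.133
87.658
88.183
88.708
89.233
89.757
90.280
90.803
91.326
91.848
92.370
92.891
93.412
93.932
94.452
94.971
95.490
96.009
96.527
97.045
97.563
98.081
98.599
99.117
99.634
100.152
100.671
101.189
101.708
102.226
102.746
103.266
103.786
104.307
104.828
105.350
105.872
106.394
106.918
107.441
107.965
108.490
109.015
109.540
110.065
110.590
111.116
111.642
112.168
112.693
113.219
113.744
114.269
114.794
115.319
115.843
116.367
116.890
117.413
117.935
118.457
118.978
119.499
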