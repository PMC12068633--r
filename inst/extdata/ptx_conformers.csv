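molecule,model,dU_kJmol,L12_A,L13_A,RC_A
1,AA,16.906,11.375,8.216,5.118
2,AA,17.54,12.479,7.513,5.293
3,AA,24.857,10.948,6.799,4.932
4,AA,2.42,11.333,6.962,5.016
5,AA,21.343,11.394,7.421,5.059
6,AA,7.462,12.032,7.112,5.143
7,AA,19.308,11.054,7.605,5.154
8,AA,40.921,11.673,6.902,5.049
9,AA,27.304,11.12,8.268,5.106
10,AA,24.003,11.77,6.645,5.144
11,AA,29.486,12.414,7.621,5.246
12,AA,4.25,11.295,9.762,4.868
13,AA,19.581,10.24,7.828,5.064
14,AA,5.286,11.019,7.356,4.999
15,AA,16.244,11.647,7.907,5.288
16,AA,16.961,11.852,7.692,5.225
17,AA,10.159,11.663,8.379,5.202
18,AA,27.01,11.431,6.197,5.244
19,AA,27.429,11.817,9.267,5.054
20,AA,22.796,10.551,7.811,4.979
21,AA,10.766,12.252,7.413,5.135
22,AA,26.638,10.807,7.046,4.93
23,AA,31.951,10.608,7.349,4.989
24,AA,30.498,10.565,6.4,4.925
25,AA,10.081,10.742,8.497,5.026
26,AA,13.624,10.984,8.281,5.097
27,AA,16.894,12.212,7.493,5.174
28,AA,0,11.726,7.243,5.031
29,AA,24.587,11.549,7.303,4.99
30,AA,16.506,11.323,6.605,4.92
31,AA,33.185,10.795,9.078,5.161
32,AA,18.381,12.73,7.862,5.084
1,CG,13.01,10.262,7.07,7.187
2,CG,50.376,12.626,5.792,7.625
3,CG,32.455,7.328,9.348,6.928
4,CG,20.122,16.051,10.892,7.186
5,CG,26.053,7.328,11.166,6.14
6,CG,39.334,13.325,11.619,6.673
7,CG,23.5,10.665,8.766,6.348
8,CG,52.827,10.124,13.865,7.099
9,CG,27.053,5.647,10.917,7.146
10,CG,43.504,10.275,11.13,6.832
11,CG,32.193,13.925,6.187,7.178
12,CG,21.352,5.668,9.963,6.689
13,CG,28.981,12.367,4.981,6.733
14,CG,12.569,11.894,5.108,6.975
15,CG,28.302,8.51,5.415,6.507
16,CG,38.986,13.156,8.872,6.345
17,CG,52.947,15.409,9.478,7.536
18,CG,53.01,17.132,10.507,7.95
19,CG,27.653,18.571,13.963,7.746
20,CG,40.243,16.687,11.915,6.381
21,CG,45.035,15.505,15.798,7.855
22,CG,0,4.941,10.005,6.318
23,CG,25.069,7.248,9.774,6.581
24,CG,42.266,11.491,11.005,6.838
25,CG,28.721,5.741,9.36,6.466
26,CG,26.662,12.157,6.017,7.216
27,CG,46.781,17.922,14.109,7.627
28,CG,30.746,12.382,6.171,6.823
29,CG,47,15.952,11.372,6.752
30,CG,13.455,8.792,6.044,6.797
31,CG,74.304,18.106,15.267,7.796
32,CG,44.859,8.954,14.101,7.673
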