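base,name,element,x,y,z
A,N9,N,-6.1555,4.4077,0.8965
A,C8,C,-4.8405,4.7987,0.9761
A,N7,N,-3.9875,3.8237,0.7777
A,C5,C,-4.7935,2.7154,0.5523
A,C6,C,-4.4955,1.3699,0.2786
A,N6,N,-3.2535,0.8908,0.1812
A,N1,N,-5.5325,0.5213,0.106
A,C2,C,-6.7765,1.0025,0.2039
A,N3,N,-7.1845,2.244,0.4564
A,C4,C,-6.1315,3.0613,0.6227
A,C1',C,-7.3435,5.2387,1.0656
A,O4',O,-6.9379,6.5933,1.0708
A,C2',C,-8.0075,5.0765,2.43
A,C3',C,-7.1339,5.9776,3.2964
A,C4',C,-6.9087,7.1904,2.3947
A,O2',O,-7.8527,3.7535,2.9044
A,O3',O,-7.7416,6.1899,4.5654
A,C5',C,-5.8498,8.1602,2.8619
A,O5',O,-4.5509,7.5406,2.8111
A,P,P,-3.2266,8.397,3.0359
A,OP1,O,-3.3734,9.1427,4.3117
A,OP2,O,-2.0782,7.4578,3.1003
G,N9,N,-6.1535,4.4597,0.9071
G,C8,C,-4.8415,4.8624,0.989
G,N7,N,-3.9945,3.8894,0.7911
G,C5,C,-4.7935,2.7762,0.5647
G,C6,C,-4.4405,1.4307,0.291
G,O6,O,-3.3105,0.9358,0.1904
G,N1,N,-5.5645,0.6281,0.1278
G,C2,C,-6.8635,1.0652,0.2167
G,N2,N,-7.8135,0.1362,0.0277
G,N3,N,-7.2065,2.3166,0.4712
G,C4,C,-6.1295,3.1133,0.6332
G,C1',C,-7.3415,5.2907,1.0761
G,O4',O,-6.9359,6.6452,1.0813
G,C2',C,-8.0055,5.1285,2.4405
G,C3',C,-7.1319,6.0295,3.3069
G,C4',C,-6.9067,7.2424,2.4052
G,O2',O,-7.8507,3.8055,2.915
G,O3',O,-7.7396,6.2419,4.576
G,C5',C,-5.8478,8.2121,2.8725
G,O5',O,-4.5489,7.5925,2.8217
G,P,P,-3.2246,8.4489,3.0465
G,OP1,O,-3.3714,9.1946,4.3223
G,OP2,O,-2.0762,7.5097,3.1109
C,N1,N,-6.1495,4.4509,0.9053
C,C2,C,-6.3365,3.0946,0.6295
C,O2,O,-7.4925,2.6546,0.54
C,N3,N,-5.2555,2.297,0.4672
C,C4,C,-4.0275,2.8105,0.5716
C,N4,N,-2.9895,1.9863,0.404
C,C5,C,-3.8085,4.1892,0.8521
C,C6,C,-4.8875,4.9663,1.0102
C,C1',C,-7.3415,5.2936,1.0767
C,O4',O,-6.9292,6.6461,1.0815
C,C2',C,-8.0049,5.1347,2.4418
C,C3',C,-7.126,6.0314,3.3073
C,C4',C,-6.8957,7.2431,2.4054
C,O2',O,-7.8562,3.811,2.9161
C,O3',O,-7.7313,6.2467,4.577
C,C5',C,-5.8315,8.2076,2.8716
C,O5',O,-4.5357,7.5816,2.8195
C,P,P,-3.207,8.4314,3.0429
C,OP1,O,-3.3488,9.1778,4.3188
C,OP2,O,-2.0632,7.4865,3.1062
U,N1,N,-6.1485,4.4097,0.8969
U,C2,C,-6.3265,3.0682,0.6241
U,O2,O,-7.4275,2.5557,0.5198
U,N3,N,-5.1665,2.3489,0.4778
U,C4,C,-3.8755,2.8261,0.5748
U,O4,O,-2.9295,2.052,0.4174
U,C5,C,-3.7755,4.2245,0.8593
U,C6,C,-4.8885,4.9516,1.0072
U,C1',C,-7.3455,5.2466,1.0672
U,O4',O,-6.9402,6.6012,1.0724
U,C2',C,-8.0095,5.0842,2.4315
U,C3',C,-7.1362,5.9855,3.298
U,C4',C,-6.9112,7.1984,2.3963
U,O2',O,-7.8545,3.7613,2.906
U,O3',O,-7.744,6.1977,4.567
U,C5',C,-5.8525,8.1684,2.8636
U,O5',O,-4.5535,7.5491,2.8129
U,P,P,-3.2294,8.4058,3.0377
U,OP1,O,-3.3764,9.1515,4.3135
U,OP2,O,-2.0808,7.4668,3.1022
PARAM,twist,,32.7,0,0
PARAM,rise,,2.81,0,0
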