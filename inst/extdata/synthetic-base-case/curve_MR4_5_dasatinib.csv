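"time_years","survival_probability"
0,1
0.204081632653061,0.995195113517272
0.408163265306122,0.983204138895433
0.612244897959184,0.958692114745525
0.816326530612245,0.94967709853163
1.02040816326531,0.93806650244258
1.22448979591837,0.908419783365637
1.42857142857143,0.906263715119456
1.63265306122449,0.887381749728753
1.83673469387755,0.864621996325502
2.04081632653061,0.844649081935221
2.24489795918367,0.821872809300304
2.44897959183673,0.809795851964919
2.6530612244898,0.793023831807873
2.85714285714286,0.768946269447885
3.06122448979592,0.760928895486896
3.26530612244898,0.750143435037082
3.46938775510204,0.728577874628504
3.6734693877551,0.710359744619193
3.87755102040816,0.703087166209495
4.08163265306122,0.673055277062603
4.28571428571429,0.671968877881056
4.48979591836735,0.649649776271733
4.69387755102041,0.636161596392587
4.89795918367347,0.609387246614786
5.10204081632653,0.601129378064176
5.30612244897959,0.590732090132101
5.51020408163265,0.567666416054629
5.71428571428571,0.552632462121645
5.91836734693878,0.54640449645844
6.12244897959184,0.534685690792766
6.3265306122449,0.51095619028766
6.53061224489796,0.49929138098873
6.73469387755102,0.493579762484453
6.93877551020408,0.476328384378333
7.14285714285714,0.474513402341412
7.3469387755102,0.467884022420689
7.55102040816327,0.444654607114098
7.75510204081633,0.429126172883143
7.95918367346939,0.419392972996808
8.16326530612245,0.410993127806756
8.36734693877551,0.400190210802596
8.57142857142857,0.394326609488309
8.77551020408163,0.387040378896878
8.97959183673469,0.362419580503844
9.18367346938776,0.348360309300093
9.38775510204082,0.345609909012031
9.59183673469388,0.342275732379352
9.79591836734694,0.340091802330143
10,0.31677471375135
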