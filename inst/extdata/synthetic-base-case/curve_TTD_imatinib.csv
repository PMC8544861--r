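"time_years","survival_probability"
0,1
0.204081632653061,0.96797946438968
0.408163265306122,0.934405762764431
0.612244897959184,0.910294016809741
0.816326530612245,0.886088177544006
1.02040816326531,0.865525427443062
1.22448979591837,0.859467429437878
1.42857142857143,0.823306594933743
1.63265306122449,0.797534335412908
1.83673469387755,0.787587014425598
2.04081632653061,0.767332757990182
2.24489795918367,0.750002245344465
2.44897959183673,0.729788090184218
2.6530612244898,0.717050366947042
2.85714285714286,0.708526167033172
3.06122448979592,0.685448794930686
3.26530612244898,0.664169113857631
3.46938775510204,0.656836738420281
3.6734693877551,0.63365540390216
3.87755102040816,0.633405946367713
4.08163265306122,0.614550850034519
4.28571428571429,0.590738250916137
4.48979591836735,0.585505026888472
4.69387755102041,0.56518983076786
4.89795918367347,0.557151968320616
5.10204081632653,0.554953126696666
5.30612244897959,0.534313503506916
5.51020408163265,0.529249823312526
5.71428571428571,0.515110939950934
5.91836734693878,0.495768501284806
6.12244897959184,0.494864027914993
6.3265306122449,0.481024298247268
6.53061224489796,0.474801797986389
6.73469387755102,0.465885992143535
6.93877551020408,0.45288496066189
7.14285714285714,0.453622392975805
7.3469387755102,0.436476979542549
7.55102040816327,0.422520722271062
7.75510204081633,0.419086486021926
7.95918367346939,0.404928924847952
8.16326530612245,0.403246133079268
8.36734693877551,0.387396343196277
8.57142857142857,0.389924836120056
8.77551020408163,0.375044051436151
8.97959183673469,0.372134996689656
9.18367346938776,0.360247870676299
9.38775510204082,0.355904839768097
9.59183673469388,0.344837874098946
9.79591836734694,0.34145965656368
10,0.334384856587435
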