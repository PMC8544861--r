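"time_years","survival_probability"
0,1
0.204081632653061,0.969599676749057
0.408163265306122,0.939946061661257
0.612244897959184,0.916385754563614
0.816326530612245,0.902745709856307
1.02040816326531,0.882976706574348
1.22448979591837,0.86259382360881
1.42857142857143,0.834548610747657
1.63265306122449,0.828926969392116
1.83673469387755,0.807983886876175
2.04081632653061,0.782315419028049
2.24489795918367,0.770561416303012
2.44897959183673,0.754233825204238
2.6530612244898,0.738356133538088
2.85714285714286,0.718991625723899
3.06122448979592,0.702027820890788
3.26530612244898,0.694807632210151
3.46938775510204,0.683267392779571
3.6734693877551,0.660847053421447
3.87755102040816,0.649150205034504
4.08163265306122,0.648382772326944
4.28571428571429,0.630292076561812
4.48979591836735,0.618620370262372
4.69387755102041,0.605484243404757
4.89795918367347,0.592253394136917
5.10204081632653,0.572014362327919
5.30612244897959,0.570332402922257
5.51020408163265,0.554048529478912
5.71428571428571,0.546095514352844
5.91836734693878,0.53916510916873
6.12244897959184,0.524483471140872
6.3265306122449,0.515361857226425
6.53061224489796,0.49284306811652
6.73469387755102,0.496358764364946
6.93877551020408,0.495753034271272
7.14285714285714,0.477084858162295
7.3469387755102,0.471106156292119
7.55102040816327,0.466448372307357
7.75510204081633,0.450322383592076
7.95918367346939,0.442515193751085
8.16326530612245,0.426532009788376
8.36734693877551,0.427035413961514
8.57142857142857,0.421133704709186
8.77551020408163,0.403255792404628
8.97959183673469,0.401025894997446
9.18367346938776,0.393366747591478
9.38775510204082,0.393118830219834
9.59183673469388,0.37364769215774
9.79591836734694,0.371762394035009
10,0.360744715699219
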