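"time_years","survival_probability"
0,1
0.204081632653061,0.996576450955389
0.408163265306122,0.99401867206591
0.612244897959184,0.987693658994247
0.816326530612245,0.980346127740355
1.02040816326531,0.974491614870832
1.22448979591837,0.97133045509429
1.42857142857143,0.965047311831571
1.63265306122449,0.966685706842785
1.83673469387755,0.96624087306329
2.04081632653061,0.947440547713048
2.24489795918367,0.945961885258473
2.44897959183673,0.94330950351544
2.6530612244898,0.946218805664676
2.85714285714286,0.931949749937196
3.06122448979592,0.94232733716106
3.26530612244898,0.930119520495861
3.46938775510204,0.92772115452356
3.6734693877551,0.920801131202193
3.87755102040816,0.920115867705497
4.08163265306122,0.917128376030594
4.28571428571429,0.912303601592053
4.48979591836735,0.902417876868029
4.69387755102041,0.901172379341238
4.89795918367347,0.896807810913233
5.10204081632653,0.888492600185505
5.30612244897959,0.890093364083243
5.51020408163265,0.876930620819836
5.71428571428571,0.878252325166897
5.91836734693878,0.879086221329715
6.12244897959184,0.871420099326357
6.3265306122449,0.868521343108272
6.53061224489796,0.866275446086343
6.73469387755102,0.861672307868142
6.93877551020408,0.860717792004501
7.14285714285714,0.864244177238463
7.3469387755102,0.850793625148949
7.55102040816327,0.844645931726411
7.75510204081633,0.850491330847061
7.95918367346939,0.836360727354965
8.16326530612245,0.839558864560193
8.36734693877551,0.837603921508521
8.57142857142857,0.833302063372364
8.77551020408163,0.825000736321681
8.97959183673469,0.822310796367611
9.18367346938776,0.814111004523283
9.38775510204082,0.814381000717422
9.59183673469388,0.808486588918085
9.79591836734694,0.80385505770508
10,0.802033326737346
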