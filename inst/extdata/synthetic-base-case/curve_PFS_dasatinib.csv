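"time_years","survival_probability"
0,1
0.204081632653061,0.995188277279251
0.408163265306122,0.977091809618239
0.612244897959184,0.983974623866237
0.816326530612245,0.977157593571111
1.02040816326531,0.977410886383206
1.22448979591837,0.96801660169695
1.42857142857143,0.961656400080771
1.63265306122449,0.960371701974605
1.83673469387755,0.953334715599343
2.04081632653061,0.948209726344005
2.24489795918367,0.957277448491857
2.44897959183673,0.94454638769591
2.6530612244898,0.935775005990323
2.85714285714286,0.932782299760754
3.06122448979592,0.9235159504873
3.26530612244898,0.931914406239395
3.46938775510204,0.91294918311447
3.6734693877551,0.913428301083705
3.87755102040816,0.912865542177992
4.08163265306122,0.907892127240224
4.28571428571429,0.907041830647083
4.48979591836735,0.887931189915273
4.69387755102041,0.887761771483568
4.89795918367347,0.884602832834669
5.10204081632653,0.881125161780617
5.30612244897959,0.879302136883549
5.51020408163265,0.867677406439916
5.71428571428571,0.863348179525602
5.91836734693878,0.860994114965199
6.12244897959184,0.862963079732232
6.3265306122449,0.852296503776348
6.53061224489796,0.848909624311578
6.73469387755102,0.844745796998116
6.93877551020408,0.840199121443149
7.14285714285714,0.829021272642277
7.3469387755102,0.835010830498011
7.55102040816327,0.827744444278508
7.75510204081633,0.819147718886366
7.95918367346939,0.815968372326917
8.16326530612245,0.812606200546661
8.36734693877551,0.809640038123953
8.57142857142857,0.812690718476001
8.77551020408163,0.803686907758045
8.97959183673469,0.806021688375696
9.18367346938776,0.799416054117528
9.38775510204082,0.78983291234685
9.59183673469388,0.78330206633209
9.79591836734694,0.781641138762782
10,0.778858641674735
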