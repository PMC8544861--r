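"time_years","survival_probability"
0,1
0.163265306122449,0.901408254902189
0.326530612244898,0.859168703237735
0.489795918367347,0.809489843262908
0.653061224489796,0.782575391003281
0.816326530612245,0.749033480496655
0.979591836734694,0.730238152635983
1.14285714285714,0.70696898353718
1.30612244897959,0.691578847587466
1.46938775510204,0.659504184374547
1.63265306122449,0.655408381769246
1.79591836734694,0.636255642185346
1.95918367346939,0.619858120142813
2.12244897959184,0.608542556812942
2.28571428571429,0.598263253952413
2.44897959183673,0.586128163456251
2.61224489795918,0.569772169509804
2.77551020408163,0.563750504548536
2.93877551020408,0.55172408928236
3.10204081632653,0.543126256234209
3.26530612244898,0.531033218753072
3.42857142857143,0.53856241194884
3.59183673469388,0.510729975016033
3.75510204081633,0.512295858383136
3.91836734693878,0.501904490367922
4.08163265306122,0.500992986490374
4.24489795918367,0.488828506696856
4.40816326530612,0.493492042697655
4.57142857142857,0.483895543661003
4.73469387755102,0.47278090610334
4.89795918367347,0.457262571103077
5.06122448979592,0.450864471210003
5.22448979591837,0.458507211898126
5.38775510204082,0.446510634939767
5.55102040816327,0.43948305981982
5.71428571428571,0.434599466255313
5.87755102040816,0.432012365231901
6.04081632653061,0.426128729126894
6.20408163265306,0.419511314805498
6.36734693877551,0.419244758660167
6.53061224489796,0.414513139801291
6.69387755102041,0.414020402661736
6.85714285714286,0.403488848774887
7.02040816326531,0.404828284995195
7.18367346938775,0.395891100663205
7.3469387755102,0.390123706106273
7.51020408163265,0.388953796874417
7.6734693877551,0.390033315194917
7.83673469387755,0.388634884149366
8,0.385800800214462
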