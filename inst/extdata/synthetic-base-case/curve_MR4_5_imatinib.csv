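"time_years","survival_probability"
0,1
0.204081632653061,0.997923796688214
0.408163265306122,0.986782213894554
0.612244897959184,0.973273917379931
0.816326530612245,0.959288317250662
1.02040816326531,0.961848279339851
1.22448979591837,0.941202318765074
1.42857142857143,0.940328524764711
1.63265306122449,0.924873603540001
1.83673469387755,0.915664768487632
2.04081632653061,0.901623002377369
2.24489795918367,0.894640033534907
2.44897959183673,0.876923362807832
2.6530612244898,0.872479460273026
2.85714285714286,0.861163236308124
3.06122448979592,0.849938499151261
3.26530612244898,0.851221983992718
3.46938775510204,0.835520363400109
3.6734693877551,0.823324417347733
3.87755102040816,0.809144096589056
4.08163265306122,0.802545032235678
4.28571428571429,0.782785472710765
4.48979591836735,0.79075843026372
4.69387755102041,0.761575981563754
4.89795918367347,0.766733705401332
5.10204081632653,0.746227917685129
5.30612244897959,0.75357681671509
5.51020408163265,0.734628896343702
5.71428571428571,0.717261191036899
5.91836734693878,0.720864314853999
6.12244897959184,0.706834259245254
6.3265306122449,0.702002271688313
6.53061224489796,0.694529929955184
6.73469387755102,0.679853783884718
6.93877551020408,0.666555044736299
7.14285714285714,0.660801525354876
7.3469387755102,0.647795613176147
7.55102040816327,0.638321923025233
7.75510204081633,0.635591587460855
7.95918367346939,0.626588831319704
8.16326530612245,0.617974216545551
8.36734693877551,0.6111014967118
8.57142857142857,0.610400900378147
8.77551020408163,0.595067314374226
8.97959183673469,0.592281016669723
9.18367346938776,0.579373570964092
9.38775510204082,0.571876687753445
9.59183673469388,0.568565085375215
9.79591836734694,0.558127523552609
10,0.551108938097541
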