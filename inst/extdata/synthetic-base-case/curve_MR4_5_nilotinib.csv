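"time_years","survival_probability"
0,1
0.204081632653061,0.982682958514443
0.408163265306122,0.964744420844766
0.612244897959184,0.947304244768296
0.816326530612245,0.92627552464548
1.02040816326531,0.909233784079165
1.22448979591837,0.882286056814503
1.42857142857143,0.866229242110632
1.63265306122449,0.837072900475937
1.83673469387755,0.821811732490258
2.04081632653061,0.794362105577988
2.24489795918367,0.774233103509864
2.44897959183673,0.758275145143317
2.6530612244898,0.73261182268734
2.85714285714286,0.703379883826489
3.06122448979592,0.691689027581577
3.26530612244898,0.674781889898818
3.46938775510204,0.65614348954291
3.6734693877551,0.638173732406531
3.87755102040816,0.613553243446602
4.08163265306122,0.597671534380564
4.28571428571429,0.578894061183886
4.48979591836735,0.552160813715043
4.69387755102041,0.547917932770195
4.89795918367347,0.518976103849976
5.10204081632653,0.509796187323934
5.30612244897959,0.486959151557261
5.51020408163265,0.46368671884453
5.71428571428571,0.463195292640148
5.91836734693878,0.452653101722587
6.12244897959184,0.424431556892532
6.3265306122449,0.403771722366133
6.53061224489796,0.404679824812061
6.73469387755102,0.388889080332117
6.93877551020408,0.363117665125808
7.14285714285714,0.358303722005727
7.3469387755102,0.345274713839874
7.55102040816327,0.336823852327606
7.75510204081633,0.328354691071333
7.95918367346939,0.311702936140296
8.16326530612245,0.299818669631625
8.36734693877551,0.291505657782031
8.57142857142857,0.282881136581217
8.77551020408163,0.268372641640479
8.97959183673469,0.26063544446509
9.18367346938776,0.246244735401593
9.38775510204082,0.248043854309211
9.59183673469388,0.242649795180269
9.79591836734694,0.221940284937742
10,0.223342095982073
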