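"time_years","survival_probability"
0,1
0.163265306122449,0.998956471901807
0.326530612244898,0.966260237856813
0.489795918367347,0.94957830416509
0.653061224489796,0.94016670577895
0.816326530612245,0.915786289977503
0.979591836734694,0.906523915585817
1.14285714285714,0.894168981630774
1.30612244897959,0.875033543198151
1.46938775510204,0.85739457971865
1.63265306122449,0.845507601506839
1.79591836734694,0.83583509121807
1.95918367346939,0.823975800127755
2.12244897959184,0.80743016469792
2.28571428571429,0.796459192730788
2.44897959183673,0.788853641469741
2.61224489795918,0.773973287109756
2.77551020408163,0.7584112202416
2.93877551020408,0.750069015826116
3.10204081632653,0.734235839761912
3.26530612244898,0.720181477789034
3.42857142857143,0.704568516810569
3.59183673469388,0.701227051369472
3.75510204081633,0.696405331166225
3.91836734693878,0.675902000333564
4.08163265306122,0.668392200910044
4.24489795918367,0.651759868404275
4.40816326530612,0.64713972598877
4.57142857142857,0.631609296790154
4.73469387755102,0.626016507379234
4.89795918367347,0.614269910692579
5.06122448979592,0.60650566406505
5.22448979591837,0.58921792762747
5.38775510204082,0.586389225253893
5.55102040816327,0.571259533157954
5.71428571428571,0.569302129611082
5.87755102040816,0.55571267492357
6.04081632653061,0.549124468670797
6.20408163265306,0.528947758113706
6.36734693877551,0.535309121220103
6.53061224489796,0.520528350171534
6.69387755102041,0.517241776577203
6.85714285714286,0.505425018983823
7.02040816326531,0.498573999726189
7.18367346938775,0.495538799694122
7.3469387755102,0.479054386715706
7.51020408163265,0.463730868898082
7.6734693877551,0.472723199746978
7.83673469387755,0.45421726739124
8,0.443268093562001
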