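"time_years","survival_probability"
0,1
0.204081632653061,0.982721101627223
0.408163265306122,0.957459630230892
0.612244897959184,0.925443947753187
0.816326530612245,0.90870953195993
1.02040816326531,0.895538954902921
1.22448979591837,0.872421696118893
1.42857142857143,0.856709444966013
1.63265306122449,0.833723992218282
1.83673469387755,0.822164951439841
2.04081632653061,0.798109411372975
2.24489795918367,0.78221360551713
2.44897959183673,0.760064311269825
2.6530612244898,0.754510730536683
2.85714285714286,0.735141315735365
3.06122448979592,0.728902383849535
3.26530612244898,0.709992901753424
3.46938775510204,0.705579973275766
3.6734693877551,0.688123849100768
3.87755102040816,0.680573630928228
4.08163265306122,0.665167319193845
4.28571428571429,0.650140159472014
4.48979591836735,0.636872606866097
4.69387755102041,0.62924219828549
4.89795918367347,0.625163409737307
5.10204081632653,0.6095482846971
5.30612244897959,0.588509567645723
5.51020408163265,0.586557270264241
5.71428571428571,0.583892537242014
5.91836734693878,0.561199592443946
6.12244897959184,0.552678141473308
6.3265306122449,0.549569676558203
6.53061224489796,0.532001757706481
6.73469387755102,0.526888163666451
6.93877551020408,0.521913432302937
7.14285714285714,0.511459049600543
7.3469387755102,0.500089522977908
7.55102040816327,0.491008385073098
7.75510204081633,0.488719546705492
7.95918367346939,0.475846825659833
8.16326530612245,0.464610316652634
8.36734693877551,0.46107423360234
8.57142857142857,0.446996389123657
8.77551020408163,0.443180491218442
8.97959183673469,0.430446306648209
9.18367346938776,0.428354752611208
9.38775510204082,0.41708328179777
9.59183673469388,0.417248181383571
9.79591836734694,0.410011303311261
10,0.406372780186367
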