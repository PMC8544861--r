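"time_years","survival_probability"
0,1
0.204081632653061,0.993467647897784
0.408163265306122,0.986178479533523
0.612244897959184,0.978580968528433
0.816326530612245,0.981081931954006
1.02040816326531,0.960121957916941
1.22448979591837,0.9646746924669
1.42857142857143,0.969071796358739
1.63265306122449,0.955902444579556
1.83673469387755,0.941887583488513
2.04081632653061,0.936262289311751
2.24489795918367,0.943365423670735
2.44897959183673,0.937380237433512
2.6530612244898,0.91561893319456
2.85714285714286,0.919641056553897
3.06122448979592,0.91559994772749
3.26530612244898,0.899587000735191
3.46938775510204,0.903724182673177
3.6734693877551,0.905780982843535
3.87755102040816,0.893493391002502
4.08163265306122,0.881146136906855
4.28571428571429,0.878520614388646
4.48979591836735,0.871767614589936
4.69387755102041,0.872640242867861
4.89795918367347,0.862623605171794
5.10204081632653,0.861702227840877
5.30612244897959,0.847422559979027
5.51020408163265,0.843714459390413
5.71428571428571,0.846977761816552
5.91836734693878,0.82781309019466
6.12244897959184,0.83444914336579
6.3265306122449,0.831863172984369
6.53061224489796,0.828621265657472
6.73469387755102,0.814266614545947
6.93877551020408,0.808543467327276
7.14285714285714,0.806964966876893
7.3469387755102,0.794841785228549
7.55102040816327,0.804772742823524
7.75510204081633,0.794366663983313
7.95918367346939,0.784470526308525
8.16326530612245,0.782079215236526
8.36734693877551,0.783376403410899
8.57142857142857,0.77122622324589
8.77551020408163,0.777008561134255
8.97959183673469,0.759459643428122
9.18367346938776,0.757008807754026
9.38775510204082,0.747917691094403
9.59183673469388,0.751431614387056
9.79591836734694,0.741271943317349
10,0.731608249604216
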