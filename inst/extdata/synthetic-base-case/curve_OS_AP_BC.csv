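"time_years","survival_probability"
0,1
0.102040816326531,0.960047160259671
0.204081632653061,0.932757191684486
0.306122448979592,0.888007776833863
0.408163265306122,0.850846499703242
0.510204081632653,0.804346332210052
0.612244897959184,0.764755526411668
0.714285714285714,0.718261666828937
0.816326530612245,0.668289037207517
0.918367346938776,0.636907093409899
1.02040816326531,0.602600528681447
1.12244897959184,0.56405599606299
1.22448979591837,0.53340451358154
1.3265306122449,0.501177857653763
1.42857142857143,0.469231845567302
1.53061224489796,0.451556303169331
1.63265306122449,0.412323220261968
1.73469387755102,0.393520450235587
1.83673469387755,0.35776714783186
1.93877551020408,0.328123774344396
2.04081632653061,0.305394228815196
2.14285714285714,0.285904043606844
2.24489795918367,0.27984737740508
2.3469387755102,0.257280791085845
2.44897959183673,0.235850032490506
2.55102040816327,0.211368376571574
2.6530612244898,0.208623535100064
2.75510204081633,0.193309700280371
2.85714285714286,0.180877816363183
2.95918367346939,0.161973063923161
3.06122448979592,0.146472984836539
3.16326530612245,0.130443671417369
3.26530612244898,0.120803856311629
3.36734693877551,0.128685133481962
3.46938775510204,0.109077773624318
3.57142857142857,0.109530324933634
3.6734693877551,0.0933424173360471
3.77551020408163,0.0861846257097616
3.87755102040816,0.0781872683325524
3.97959183673469,0.084697423199222
4.08163265306122,0.0779087672451672
4.18367346938776,0.0651336067632023
4.28571428571429,0.06369792849982
4.38775510204082,0.0547789022861982
4.48979591836735,0.0489004918879919
4.59183673469388,0.0403152100543417
4.69387755102041,0.0500384918872662
4.79591836734694,0.0339192605958338
4.89795918367347,0.039250930575702
5,0.032729705996106
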