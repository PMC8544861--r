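"age","sex","qx"
0,"male",0.000529859574809555
1,"male",0.000532683302357451
2,"male",0.000535772943284663
3,"male",0.0005391535379905
4,"male",0.000542852484680889
5,"male",0.000546899761342035
6,"male",0.000551328168606591
7,"male",0.000556173595472997
8,"male",0.000561475310030035
9,"male",0.00056727627753661
10,"male",0.000573623508427157
11,"male",0.000580568439057072
12,"male",0.000588167348263502
13,"male",0.000596481813106675
14,"male",0.00060557920747184
15,"male",0.000615533247557587
16,"male",0.000626424588650809
17,"male",0.000638341478002458
18,"male",0.000651380469067986
19,"male",0.000665647202867214
20,"male",0.000681257262756363
21,"male",0.000698337109492075
22,"male",0.000717025104108537
23,"male",0.000737472626828439
24,"male",0.000759845300993822
25,"male",0.000784324331837838
26,"male",0.000811107970828617
27,"male",0.000840413117311756
28,"male",0.000872477070262057
29,"male",0.000907559444138117
30,"male",0.000945944264123533
31,"male",0.00098794225744292
32,"male",0.00103389335897519
33,"male",0.00108416945104983
34,"male",0.00113917735913194
35,"male",0.00119936212707261
36,"male",0.00126521059775231
37,"male",0.00133725532727524
38,"male",0.00141607886340678
39,"male",0.00150231842169879
40,"male",0.00159667099572036
41,"male",0.00169989894104872
42,"male",0.00181283607615756
43,"male",0.00193639434712078
44,"male",0.0020715711071172
45,"male",0.00221945706611126
46,"male",0.00238124497080405
47,"male",0.0025582390800174
48,"male",0.0027518655061014
49,"male",0.00296368349876053
50,"male",0.00319539775387478
51,"male",0.00344887183646581
52,"male",0.0037261428139076
53,"male",0.00402943720281312
54,"male",0.00436118834071197
55,"male",0.00472405530164399
56,"male",0.00512094348308545
57,"male",0.00555502700012911
58,"male",0.00602977303147723
59,"male",0.00654896827045037
60,"male",0.00711674764273162
61,"male",0.00773762546074186
62,"male",0.00841652919215852
63,"male",0.00915883602682355
64,"male",0.0099704124317691
65,"male",0.0108576568878567
66,"male",0.0118275460030035
67,"male",0.0128876841954659
68,"male",0.0140463571353246
69,"male",0.0153125891221522
70,"male",0.0166962045606269
71,"male",0.0182078936721322
72,"male",0.0198592825474145
73,"male",0.0216630076011315
74,"male",0.0236327944311739
75,"male",0.02578354101119
76,"male",0.0281314050504633
77,"male",0.0306938952373934
78,"male",0.0334899659369029
79,"male",0.0365401147331279
80,"male",0.0398664819910487
81,"male",0.0434929513478971
82,"male",0.0474452497301651
83,"male",0.0517510451170737
84,"male",0.0564400398281335
85,"male",0.0615440565921989
86,"male",0.0670971140492804
87,"male",0.0731354876356863
88,"male",0.0796977509999311
89,"male",0.0868247921850253
90,"male",0.0945597977885981
91,"male",0.102948197176313
92,"male",0.112037557582601
93,"male",0.121877419600641
94,"male",0.132519061166745
95,"male",0.144015176723959
96,"male",0.156419456865972
97,"male",0.1697860525003
98,"male",0.184168906544201
99,"male",0.199620935529569
100,"male",0.216193043438961
0,"female",0.000314950392708901
1,"female",0.000316444803604821
2,"female",0.000318088143200779
3,"female",0.000319895253020785
4,"female",0.000321882453565348
5,"female",0.000324067691680585
6,"female",0.000326470702610049
7,"female",0.000329113188189067
8,"female",0.000332019012791784
9,"female",0.000335214418796359
10,"female",0.000338728263513333
11,"female",0.000342592279713005
12,"female",0.000346841362100725
13,"female",0.000351513882324128
14,"female",0.00035665203535018
15,"female",0.000362302220335287
16,"female",0.000368515459418739
17,"female",0.000375347858212693
18,"female",0.000382861112136479
19,"female",0.000391123063152365
20,"female",0.000400208311914674
21,"female",0.000410198890839153
22,"female",0.000421185004147229
23,"female",0.000433265841536246
24,"female",0.000446550472788854
25,"female",0.00046115883135478
26,"female",0.000477222795735477
27,"female",0.00049488737836989
28,"female",0.000514312032681152
29,"female",0.00053567208999139
30,"female",0.000559160339165921
31,"female",0.000584988763111194
32,"female",0.000613390447641415
33,"female",0.000644621679744217
34,"female",0.000678964253949754
35,"female",0.000716728007328249
36,"female",0.000758253605648851
37,"female",0.000803915605419148
38,"female",0.000854125818928186
39,"female",0.000909337012039657
40,"female",0.000970046967350036
41,"female",0.00103680294846675
42,"female",0.00111020660458572
43,"female",0.00119091935828375
44,"female",0.00127966832352255
45,"female",0.00137725280529688
46,"female",0.00148455143719539
47,"female",0.00160253001839505
48,"female",0.00173225011731359
49,"female",0.00187487851532753
50,"female",0.00203169757065491
51,"female",0.00220411658972974
52,"female",0.0023936843011928
53,"female",0.00260210253599713
54,"female",0.00283124122612521
55,"female",0.00308315484401767
56,"female",0.00336010041505574
57,"female",0.00366455724630144
58,"female",0.00399924852615818
59,"female",0.0043671649616458
60,"female",0.0047715906325162
61,"female",0.00521613125437603
62,"female",0.00570474505621676
63,"female",0.00624177649108726
64,"female",0.00683199301186499
65,"female",0.00748062515687575
66,"female",0.00819341020209297
67,"female",0.00897663964732609
68,"female",0.00983721081255862
69,"female",0.0107826828266362
70,"female",0.0118213372928903
71,"female",0.0129622439138052
72,"female",0.0142153313480561
73,"female",0.0155914635563967
74,"female",0.0171025218657975
75,"female",0.018761492941369
76,"female",0.0205825627998277
77,"female",0.0225812169228942
78,"female",0.0247743464296573
79,"female",0.0271803601384346
80,"female",0.0298193021849141
81,"female",0.0327129746573513
82,"female",0.0358850644531175
83,"female",0.0393612732446404
84,"female",0.0431694490561323
85,"female",0.0473397174836139
86,"female",0.0519046100265512
87,"female",0.0568991863257549
88,"female",0.062361146304126
89,"female",0.0683309272691215
90,"female",0.0748517799436167
91,"female",0.0819698161319167
92,"female",0.0897340192897581
93,"female",0.0981962076463123
94,"female",0.107410937725556
95,"female",0.117435334148949
96,"female",0.128328829502968
97,"female",0.14015279587843
98,"female",0.15297004751894
99,"female",0.166844191978005
100,"female",0.18183880545325
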