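n,alpha,d_crit,n_null,l0,seed
66,0.1,0.303030303030303,3000,33,20260920
66,0.05,0.303030303030303,3000,33,20260920
66,0.02,0.363636363636364,3000,33,20260920
66,0.01,0.393939393939394,3000,33,20260920
66,0.005,0.394090909090912,3000,33,20260920
90,0.1,0.31,3000,33,20260920
90,0.05,0.337208747135218,3000,33,20260920
90,0.02,0.367604003328893,3000,33,20260920
90,0.01,0.387644544997486,3000,33,20260920
90,0.005,0.420005263157895,3000,33,20260920
128,0.1,0.292187832446246,3000,33,20260920
128,0.05,0.313878283878284,3000,33,20260920
128,0.02,0.346043311527183,3000,33,20260920
128,0.01,0.365917083854818,3000,33,20260920
128,0.005,0.381180472752304,3000,33,20260920
180,0.1,0.277450745663915,3000,33,20260920
180,0.05,0.298165431500895,3000,33,20260920
180,0.02,0.32734897984898,3000,33,20260920
180,0.01,0.349049680478252,3000,33,20260920
180,0.005,0.358669527712081,3000,33,20260920
256,0.1,0.264167288316589,3000,33,20260920
256,0.05,0.284259259259259,3000,33,20260920
256,0.02,0.309500884784451,3000,33,20260920
256,0.01,0.325387601697282,3000,33,20260920
256,0.005,0.341490771628231,3000,33,20260920
360,0.1,0.256672976342015,3000,33,20260920
360,0.05,0.277782790007619,3000,33,20260920
360,0.02,0.300931806233319,3000,33,20260920
360,0.01,0.319209224835393,3000,33,20260920
360,0.005,0.336704926327517,3000,33,20260920
512,0.1,0.255748388206287,3000,33,20260920
512,0.05,0.275131270955906,3000,33,20260920
512,0.02,0.300027565838051,3000,33,20260920
512,0.01,0.318164851276837,3000,33,20260920
512,0.005,0.339987663693301,3000,33,20260920
724,0.1,0.249128170534449,3000,33,20260920
724,0.05,0.268883205456096,3000,33,20260920
724,0.02,0.294743674077972,3000,33,20260920
724,0.01,0.307813432647472,3000,33,20260920
724,0.005,0.322305906166441,3000,33,20260920
1024,0.1,0.246131528929002,3000,33,20260920
1024,0.05,0.267796031784576,3000,33,20260920
1024,0.02,0.294476465344276,3000,33,20260920
1024,0.01,0.308324420677362,3000,33,20260920
1024,0.005,0.315818967804784,3000,33,20260920
1448,0.1,0.247206884105698,3000,33,20260920
1448,0.05,0.270729411317472,3000,33,20260920
1448,0.02,0.293975372095513,3000,33,20260920
1448,0.01,0.312219780624264,3000,33,20260920
1448,0.005,0.326156159805744,3000,33,20260920
2048,0.1,0.241130012356654,3000,33,20260920
2048,0.05,0.261359547362983,3000,33,20260920
2048,0.02,0.287285177821957,3000,33,20260920
2048,0.01,0.306098654034138,3000,33,20260920
2048,0.005,0.32044828831358,3000,33,20260920
2896,0.1,0.240377226685295,1500,33,20260920
2896,0.05,0.260549778010517,1500,33,20260920
2896,0.02,0.281385813795053,1500,33,20260920
2896,0.01,0.300604490354171,1500,33,20260920
2896,0.005,0.322549399866637,1500,33,20260920
4096,0.1,0.243751417967676,1500,33,20260920
4096,0.05,0.265746965928897,1500,33,20260920
4096,0.02,0.290568098441355,1500,33,20260920
4096,0.01,0.305698809118278,1500,33,20260920
4096,0.005,0.321826823485212,1500,33,20260920
5792,0.1,0.24032953671307,1500,33,20260920
5792,0.05,0.259343803963499,1500,33,20260920
5792,0.02,0.282147679258289,1500,33,20260920
5792,0.01,0.297511667958374,1500,33,20260920
5792,0.005,0.306028823225249,1500,33,20260920
8192,0.1,0.240996605302886,1500,33,20260920
8192,0.05,0.260769190353596,1500,33,20260920
8192,0.02,0.281665429322498,1500,33,20260920
8192,0.01,0.303475730463106,1500,33,20260920
8192,0.005,0.316137964605213,1500,33,20260920
11586,0.1,0.243912398752385,600,33,20260920
11586,0.05,0.26220084120906,600,33,20260920
11586,0.02,0.288249914215099,600,33,20260920
11586,0.01,0.299339880235751,600,33,20260920
11586,0.005,0.318251853342255,600,33,20260920
16384,0.1,0.249965783358233,600,33,20260920
16384,0.05,0.2622996745966,600,33,20260920
16384,0.02,0.278501636661484,600,33,20260920
16384,0.01,0.292562349073266,600,33,20260920
16384,0.005,0.312117646478289,600,33,20260920
23170,0.1,0.238644831313039,400,33,20260920
23170,0.05,0.255634003565558,400,33,20260920
23170,0.02,0.28438893555473,400,33,20260920
23170,0.01,0.292254643491152,400,33,20260920
23170,0.005,0.305768132114244,400,33,20260920
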