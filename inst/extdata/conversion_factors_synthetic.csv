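effective_diameter,ssde_factor,ed_factor
8,1.5148876,0.072059501
9,1.5099583,0.06806182
10,1.505045,0.064285921
11,1.5001477,0.060719499
12,1.4952663,0.057350933
13,1.4904008,0.054169247
14,1.4855511,0.051164073
15,1.4807172,0.048325618
16,1.4758991,0.045644634
17,1.4710966,0.043112383
18,1.4663097,0.040720616
19,1.4615385,0.038461538
20,1.4567827,0.036327789
21,1.4520424,0.034312414
22,1.4473176,0.032408847
23,1.4426081,0.030610885
24,1.437914,0.02891267
25,1.4332351,0.027308667
26,1.4285714,0.025793651
27,1.423923,0.024362684
28,1.4192896,0.023011103
29,1.4146713,0.021734504
30,1.4100681,0.020528729
31,1.4054798,0.019389846
32,1.4009065,0.018314146
33,1.396348,0.017298123
34,1.3918044,0.016338466
35,1.3872755,0.015432049
36,1.3827614,0.014575918
37,1.378262,0.013767282
38,1.3737773,0.013003508
39,1.3693071,0.012282106
40,1.3648514,0.011600725
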