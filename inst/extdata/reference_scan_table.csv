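id,phantom,kvp,ma,mas,ctdi_vol,cnr,snr,median_steepness
1,adult,140,50,14.00,1.59,18.64,17.27,5324.49
2,adult,140,40,11.20,1.20,17.25,16.06,3995.02
3,adult,140,30,8.40,0.95,16.35,15.22,2673.91
4,adult,140,20,5.60,0.63,15.58,14.46,2195.73
5,adult,140,10,2.80,0.32,13.19,12.19,1297.25
6,adult,120,20,5.60,0.44,14.15,13.14,1590.85
7,adult,120,10,2.80,0.22,13.03,11.99,885.54
8,adult,100,20,5.60,0.27,13.40,12.33,937.71
9,adult,100,10,2.80,0.14,12.30,11.43,713.28
10,adult,80,20,5.60,0.14,11.24,10.47,572.30
11,adult,80,10,2.80,0.07,9.78,9.85,474.95
12,adult,70,20,5.60,0.09,10.51,10.68,397.29
13,adult,70,10,2.80,0.04,7.17,8.39,257.97
14,paediatric,140,50,14.00,1.43,24.30,24.36,3451.98
15,paediatric,140,40,11.20,1.14,24.91,25.01,3271.14
16,paediatric,140,30,8.40,0.86,22.08,22.16,3070.61
17,paediatric,140,20,5.60,0.57,17.96,17.99,2681.34
18,paediatric,140,10,2.80,0.29,16.12,16.08,1962.56
19,paediatric,120,20,5.60,0.40,15.06,15.25,2318.57
20,paediatric,120,10,2.80,0.20,14.96,15.15,1505.04
21,paediatric,100,20,5.60,0.25,14.88,15.24,1775.20
22,paediatric,100,10,2.80,0.13,15.16,15.46,1139.83
23,paediatric,80,20,5.60,0.13,12.89,13.46,1195.68
24,paediatric,80,10,2.80,0.07,11.84,12.26,685.00
25,paediatric,70,20,5.60,0.09,11.64,12.27,743.76
26,paediatric,70,10,2.80,0.04,9.63,10.33,651.23
27,neonate,140,50,14.00,1.19,75.46,74.09,2478.05
28,neonate,140,40,11.20,0.95,66.58,65.45,2477.14
29,neonate,140,30,8.40,0.71,55.17,54.02,2455.41
30,neonate,140,20,5.60,0.48,45.74,45.03,2601.04
31,neonate,140,10,2.80,0.24,36.22,35.39,2399.42
32,neonate,120,20,5.60,0.33,42.33,41.80,2386.29
33,neonate,120,10,2.80,0.17,30.80,30.34,2084.18
34,neonate,100,20,5.60,0.21,34.33,33.90,2375.71
35,neonate,100,10,2.80,0.10,27.07,26.99,2089.35
36,neonate,80,20,5.60,0.11,27.52,27.54,2082.85
37,neonate,80,10,2.80,0.06,21.06,21.04,1690.77
38,neonate,70,20,5.60,0.07,24.80,25.06,1824.99
39,neonate,70,10,2.80,0.04,18.91,19.19,1101.76
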