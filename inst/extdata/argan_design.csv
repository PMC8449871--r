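run,block,oil_pct,starch_pct,caseinate_pct,stir_rpm,stir_min,size_t0_um,size_t5_um,creaming_class
1,1,10,0,0,20000,5,15.87,28.56,2
2,1,15,0.75,1,15000,12.5,29.34,42.17,2
3,1,20,0,2,10000,20,58.32,67.04,1
4,1,20,0,0,10000,5,55.62,115.4,1
5,1,20,0,2,20000,5,20.52,24.8,2
6,1,20,1.5,0,20000,5,12.58,20.62,2
7,1,10,1.5,2,10000,5,56.22,66.65,1
8,1,10,1.5,0,20000,20,11.41,12.49,3
9,2,15,0.75,1,15000,12.5,23.6,31.96,2
10,2,10,1.5,2,20000,5,10.9,11.67,4
11,2,20,0,0,20000,20,14.01,15.63,3
12,2,10,0,2,10000,5,64.82,77.82,1
13,2,10,1.5,0,10000,5,48.14,65.65,1
14,2,10,1.5,2,10000,20,20.71,25.25,2
15,2,20,1.5,2,10000,5,21.8,30.34,1
16,2,15,0.75,1,15000,12.5,26.45,33.17,2
17,3,20,1.5,0,10000,20,24.77,31.06,2
18,3,10,0,2,20000,20,12.66,13.79,3
19,3,10,1.5,0,20000,5,22.23,43.39,1
20,3,20,1.5,0,10000,5,31.24,45.66,1
21,3,20,0,0,20000,5,12.81,35.82,2
22,3,20,0,2,10000,5,59.69,108.19,1
23,3,10,0,0,10000,20,15.16,35.7,1
24,3,20,1.5,2,20000,20,11.24,11.27,5
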