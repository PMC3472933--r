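# GZP6 source No. 3 reference data: Monte Carlo radial dose function g(r) (reference table 5)
r_cm,g
1,1.000
1.5,0.983
2,0.976
2.5,0.968
3,0.959
3.5,0.950
4,0.943
4.5,0.932
5,0.921
6,0.909
7,0.890
8,0.876
9,0.851
10,0.831
12,0.785
13,0.767
15,0.679
20,0.539
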