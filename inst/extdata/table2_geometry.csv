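# GZP6 source No. 3 reference data: line-source geometry function G_L(r,theta)*r^2, dimensionless (reference table 2)
r_cm,0,10,20,30,40,50,60,70,80,90
0.5,1.037,1.036,1.031,1.024,1.016,1.008,1.000,0.994,0.990,0.988
0.75,1.016,1.016,1.014,1.011,1.007,1.003,1.000,0.997,0.995,0.995
1,1.009,1.009,1.008,1.006,1.004,1.002,1.000,0.998,0.997,0.997
1.5,1.004,1.004,1.003,1.003,1.002,1.001,1.000,0.999,0.999,0.999
2,1.002,1.002,1.002,1.002,1.001,1.000,1.000,1.000,0.999,0.999
2.5,1.001,1.001,1.001,1.001,1.001,1.000,1.000,1.000,1.000,1.000
3,1.001,1.001,1.001,1.001,1.000,1.000,1.000,1.000,1.000,1.000
3.5,1.001,1.001,1.001,1.000,1.000,1.000,1.000,1.000,1.000,1.000
4,1.001,1.001,1.000,1.000,1.000,1.000,1.000,1.000,1.000,1.000
4.5,1.000,1.000,1.000,1.000,1.000,1.000,1.000,1.000,1.000,1.000
5,1.000,1.000,1.000,1.000,1.000,1.000,1.000,1.000,1.000,1.000
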