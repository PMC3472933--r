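# GZP6 source No. 3 reference data: Monte Carlo 2D anisotropy function F(r,theta); empty cells were not tabulated (reference table 6)
r_cm,theta_deg,F
1,0,0.858
1,10,
1,20,0.990
1,30,
1,40,0.992
1,50,
1,60,1.011
1,70,
1,80,1.025
1,90,1.000
1,100,0.995
1,110,
1,120,0.978
1,130,
1,140,1.019
1,150,
1,160,
1,170,
2,0,0.849
2,10,0.893
2,20,0.956
2,30,0.973
2,40,0.990
2,50,0.989
2,60,0.990
2,70,0.995
2,80,0.994
2,90,1.000
2,100,1.000
2,110,0.998
2,120,0.993
2,130,0.995
2,140,0.992
2,150,0.977
2,160,0.958
2,170,
3,0,0.863
3,10,0.898
3,20,0.957
3,30,0.974
3,40,0.988
3,50,0.986
3,60,0.985
3,70,1.000
3,80,0.995
3,90,1.000
3,100,1.004
3,110,1.001
3,120,0.995
3,130,0.998
3,140,0.992
3,150,0.979
3,160,0.958
3,170,0.881
4,0,0.904
4,10,0.901
4,20,0.957
4,30,0.970
4,40,0.989
4,50,0.990
4,60,0.982
4,70,1.002
4,80,0.992
4,90,1.000
4,100,1.004
4,110,0.999
4,120,0.993
4,130,0.998
4,140,0.990
4,150,0.978
4,160,0.956
4,170,0.876
5,0,0.927
5,10,0.893
5,20,0.959
5,30,0.970
5,40,0.991
5,50,0.999
5,60,0.995
5,70,1.010
5,80,1.001
5,90,1.000
5,100,1.007
5,110,1.001
5,120,1.001
5,130,1.004
5,140,0.998
5,150,0.984
5,160,0.963
5,170,0.884
10,0,0.913
10,10,0.870
10,20,0.963
10,30,0.998
10,40,0.994
10,50,1.002
10,60,1.001
10,70,1.005
10,80,1.007
10,90,1.000
10,100,1.006
10,110,1.010
10,120,1.015
10,130,1.000
10,140,0.993
10,150,0.995
10,160,0.954
10,170,0.883
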