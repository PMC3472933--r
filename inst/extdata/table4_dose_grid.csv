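# gzp6dose-grid v1 unit=cGy/h/U
z_cm\y_cm,0,0.25,0.5,0.75,1,1.5,2,2.5,3,4,5,6,8,10,14
14,0.00366,0.00348,0.00349,0.00351,0.00355,0.00360,0.00362,0.00364,0.00361,0.00356,0.00346,0.00330,0.00293,0.00251,0.00179
10,0.00776,0.00747,0.00753,0.00762,0.00775,0.00782,0.00783,0.00779,0.00765,0.00731,0.00683,0.00627,0.00512,0.00408,0.00257
8,0.01268,0.01233,0.01242,0.01259,0.01268,0.01272,0.01271,0.01249,0.01216,0.01122,0.01007,0.00893,0.00679,0.00517,0.00301
6,0.02344,0.02289,0.02322,0.02358,0.02372,0.02358,0.02300,0.02212,0.02088,0.01808,0.01534,0.01284,0.00901,0.00640,0.00347
5,0.03438,0.03373,0.03461,0.03494,0.03486,0.03422,0.03282,0.03072,0.02829,0.02343,0.01902,0.01544,0.01029,0.00706,0.00369
4,0.05513,0.05436,0.05559,0.05558,0.05527,0.05295,0.04905,0.04425,0.03936,0.03047,0.02357,0.01838,0.01156,0.00768,0.00387
3,0.10007,0.09995,0.10120,0.10029,0.09802,0.08880,0.07717,0.06576,0.05547,0.03962,0.02874,0.02139,0.01277,0.00825,0.00404
2.5,0.14581,0.14691,0.14702,0.14424,0.13804,0.11895,0.09868,0.08070,0.06597,0.04472,0.03140,0.02291,0.01334,0.00848,0.00411
2,0.23037,0.23371,0.23087,0.22057,0.20321,0.16323,0.12726,0.09901,0.07780,0.04994,0.03406,0.02428,0.01382,0.00869,0.00416
1.5,0.41507,0.42096,0.40432,0.36373,0.31538,0.22747,0.16335,0.11957,0.09008,0.05494,0.03631,0.02549,0.01423,0.00886,0.00421
1,0.96404,0.95030,0.82069,0.65489,0.51070,0.31436,0.20414,0.14060,0.10142,0.05909,0.03812,0.02642,0.01452,0.00897,0.00424
0.75,-,1.64251,1.25332,0.90067,0.64913,0.36206,0.22361,0.14951,0.10613,0.06068,0.03887,0.02673,0.01461,0.00903,0.00426
0.5,-,3.24317,1.98378,1.22459,0.80260,0.40566,0.23943,0.15679,0.10993,0.06193,0.03931,0.02696,0.01469,0.00905,0.00427
0.25,-,7.37207,3.01733,1.55687,0.93343,0.43739,0.25079,0.16130,0.11215,0.06268,0.03962,0.02714,0.01475,0.00907,0.00427
0,-,12.32321,3.63819,1.71023,0.98796,0.44908,0.25446,0.16313,0.11306,0.06297,0.03976,0.02718,0.01481,0.00910,0.00427
-0.25,-,7.37187,3.01661,1.55670,0.93376,0.43736,0.25056,0.16142,0.11212,0.06262,0.03961,0.02716,0.01476,0.00907,0.00427
-0.5,-,3.24423,1.98345,1.22515,0.80214,0.40577,0.23968,0.15661,0.10981,0.06196,0.03935,0.02695,0.01470,0.00905,0.00426
-0.75,-,1.64362,1.25309,0.90124,0.64938,0.36188,0.22361,0.14959,0.10621,0.06073,0.03882,0.02675,0.01466,0.00903,0.00425
-1,-,0.95463,0.82232,0.65543,0.51092,0.31428,0.20416,0.14068,0.10151,0.05911,0.03812,0.02639,0.01452,0.00897,0.00424
-1.5,-,0.41756,0.40609,0.36472,0.31569,0.22760,0.16345,0.11980,0.09005,0.05499,0.03636,0.02548,0.01421,0.00885,0.00420
-2,-,0.22359,0.23240,0.22150,0.20379,0.16334,0.12738,0.09904,0.07777,0.04997,0.03406,0.02431,0.01383,0.00869,0.00416
-2.5,-,0.13517,0.14677,0.14507,0.13834,0.11910,0.09893,0.08086,0.06605,0.04477,0.03147,0.02295,0.01334,0.00849,0.00411
-3,-,0.08853,0.09925,0.10101,0.09848,0.08899,0.07729,0.06578,0.05563,0.03965,0.02878,0.02145,0.01280,0.00825,0.00405
-4,-,0.04431,0.05223,0.05502,0.05557,0.05320,0.04907,0.04429,0.03938,0.03057,0.02360,0.01836,0.01156,0.00768,0.00388
-5,-,0.02532,0.03133,0.03368,0.03451,0.03434,0.03291,0.03077,0.02835,0.02347,0.01907,0.01545,0.01028,0.00706,0.00369
-6,-,0.01587,0.02029,0.02213,0.02306,0.02367,0.02307,0.02216,0.02090,0.01808,0.01534,0.01289,0.00902,0.00641,0.00348
-8,-,0.00756,0.00999,0.01126,0.01192,0.01256,0.01270,0.01251,0.01219,0.01124,0.01008,0.00894,0.00683,0.00516,0.00302
-10,-,0.00423,0.00571,0.00654,0.00701,0.00753,0.00771,0.00777,0.00768,0.00734,0.00683,0.00627,0.00511,0.00408,0.00257
-14,-,0.00183,0.00244,0.00279,0.00305,0.00333,0.00346,0.00355,0.00358,0.00356,0.00347,0.00331,0.00293,0.00251,0.00178
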