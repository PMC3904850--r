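id,structure,manual_volume,labs_volume,dice,hausdorff,volume_ratio
HC1,midbrain,5693,4981,0.907,2.72,0.875
HC2,midbrain,3733,3380,0.927,3.4,0.905
HC3,midbrain,4487,3899,0.888,1.02,0.868
HC4,midbrain,4124,3998,0.919,2.91,0.969
HC5,midbrain,3280,3153,0.919,2.43,0.961
HC6,midbrain,5234,4922,0.927,2.21,0.940
HC7,midbrain,3710,3636,0.94,2.9,0.980
HC8,midbrain,3572,3678,0.919,2.87,1.03
HC9,midbrain,2598,3678,0.818,3.58,1.41
HC10,midbrain,1978,2890,0.78,3.64,1.461
HC11,midbrain,3960,3876,0.916,3.607,0.978
HC12,midbrain,5165,4957,0.89,3.47,0.959
HC13,midbrain,5940,5269,0.89,3.59,0.887
HC14,midbrain,5000,4632,0.927,3.42,0.926
HC15,midbrain,3427,3430,0.931,1.11,1.0
HC16,midbrain,3990,3546,0.917,3.1,0.888
HC17,midbrain,2931,2721,0.887,2.56,0.928
HC18,midbrain,4564,4712,0.91,3.2,1.032
HC19,midbrain,3192,3028,0.945,2.4,0.948
HC20,midbrain,4012,3722,0.925,2.1,0.927
HC21,midbrain,4810,4849,0.909,2.89,1.008
HC22,midbrain,5224,5495,0.88,2.78,1.051
HC23,midbrain,4472,4642,0.912,3.67,1.038
HC24,midbrain,3803,3441,0.931,2.21,0.904
HC25,midbrain,3664,3897,0.904,3.16,1.063
HC26,midbrain,3930,3897,0.92,4.21,0.991
HC27,midbrain,4004,4432,0.9,3.14,1.106
HC28,midbrain,4419,4485,0.91,3.128,1.014
HC29,midbrain,4461,4617,0.88,2.72,1.034
HC30,midbrain,3321,3085,0.91,2.68,0.928
HC1,pons,10610,10248,0.941,1.121,0.965
HC2,pons,10541,10341,0.942,1.4,0.981
HC3,pons,10337,10701,0.955,1.226,1.035
HC4,pons,9698,9532,0.958,0.99,0.982
HC5,pons,8907,9284,0.952,1.306,1.042
HC6,pons,10863,11351,0.946,1.4271,1.045
HC7,pons,10043,9935,0.97,0.72,0.989
HC8,pons,9948,10571,0.956,0.86,1.062
HC9,pons,10441,10630,0.952,1.335,1.018
HC10,pons,8541,8610,0.964,0.79,1.008
HC11,pons,11056,10899,0.963,1.24,0.985
HC12,pons,10784,11229,0.961,0.84,1.041
HC13,pons,10705,11048,0.961,0.8481,1.032
HC14,pons,10673,11241,0.8,8.45,1.053
HC15,pons,10919,11239,0.957,1.69,1.029
HC16,pons,11829,11740,0.961,0.75,0.992
HC17,pons,6936,7416,0.948,2.23,1.069
HC18,pons,8752,9411,0.945,1.91,1.075
HC19,pons,11551,11571,0.951,1.11,1.0017
HC20,pons,10234,10375,0.967,5.86,1.013
HC21,pons,10035,10185,0.964,6.74,1.015
HC22,pons,10177,10218,0.96,1.62,1.004
HC23,pons,9252,9313,0.945,0.77,1.006
HC24,pons,9874,9918,0.964,7.65,1.0044
HC25,pons,8469,10678,0.874,1.443,1.26
HC26,pons,11852,11684,0.954,1.44,0.985
HC27,pons,10874,11088,0.959,1.57,1.019
HC28,pons,9177,9172,0.974,1.31,0.999
HC29,pons,11538,11716,0.962,1.03,1.015
HC30,pons,11959,11868,0.975,1.32,0.992
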