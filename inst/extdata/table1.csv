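id,structure,manual_volume,labs_volume,dice,hausdorff,volume_ratio
HC1,midbrain,5256,4981,0.935,2.23,0.948
HC2,midbrain,3608,3380,0.943,2.96,0.937
HC3,midbrain,4377,3899,0.927,2.99,0.891
HC4,midbrain,4182,3998,0.939,2.64,0.956
HC5,midbrain,3314,3153,0.927,2.76,0.951
HC6,midbrain,5172,4922,0.927,2.53,0.952
HC7,midbrain,3864,3636,0.942,2.57,0.941
HC8,midbrain,3633,3678,0.921,3.34,1.012
HC9,midbrain,2834,3678,0.868,4.16,1.298
HC10,midbrain,1997,2890,0.79,3.58,1.447
HC11,midbrain,3950,3876,0.923,3.65,0.981
HC12,midbrain,5393,4957,0.879,3.68,0.919
HC13,midbrain,6124,5269,0.884,3.1,0.860
HC14,midbrain,4899,4632,0.931,2.3,0.945
HC15,midbrain,3354,3430,0.903,0.77,1.023
HC16,midbrain,3921,3546,0.921,2.75,0.904
HC17,midbrain,2842,2721,0.896,3.41,0.957
HC18,midbrain,4415,4712,0.906,3.75,1.067
HC19,midbrain,3164,3028,0.955,2.98,0.957
HC20,midbrain,3923,3722,0.935,2.56,0.949
HC21,midbrain,4720,4849,0.917,3.17,1.027
HC22,midbrain,5510,5495,0.936,2.18,0.997
HC23,midbrain,4379,4642,0.924,3.79,1.060
HC24,midbrain,3684,3441,0.943,2.206,0.934
HC25,midbrain,3679,3897,0.911,3.58,1.059
HC26,midbrain,3900,3897,0.939,4.82,0.999
HC27,midbrain,4245,4432,0.906,3.14,1.044
HC28,midbrain,4305,4485,0.875,3.21,1.042
HC29,midbrain,4709,4617,0.922,3.12,0.980
HC30,midbrain,3365,3085,0.885,2.2,0.917
HC1,pons,10178,10248,0.956,0.9054,1.007
HC2,pons,10144,10341,0.940,1.525,1.019
HC3,pons,10160,10701,0.923,1.5776,1.053
HC4,pons,9238,9532,0.943,1.323,1.032
HC5,pons,8875,9284,0.940,1.9243,1.046
HC6,pons,10795,11351,0.931,1.7847,1.052
HC7,pons,8934,9935,0.934,1.4925,1.112
HC8,pons,9435,10571,0.942,1.206,1.120
HC9,pons,9829,10630,0.934,1.137,1.081
HC10,pons,8348,8610,0.963,1.5,1.031
HC11,pons,11221,10899,0.959,0.831,0.971
HC12,pons,10624,11229,0.942,1.6461,1.057
HC13,pons,10411,11048,0.947,1.3645,1.061
HC14,pons,8629,11241,0.77,9.1,1.303
HC15,pons,11416,11239,0.968,1.01,0.984
HC16,pons,11904,11740,0.956,0.86,0.986
HC17,pons,7334,7416,0.941,1.82,1.011
HC18,pons,8822,9411,0.941,2.1,1.067
HC19,pons,11487,11571,0.954,1.264,1.007
HC20,pons,10382,10375,0.953,1.76,0.999
HC21,pons,9943,10185,0.938,1.4906,1.024
HC22,pons,9921,10218,0.945,2.05,1.030
HC23,pons,9239,9313,0.932,1.479,1.008
HC24,pons,10002,9918,0.942,8.2,0.992
HC25,pons,8549,10678,0.855,2.13,1.249
HC26,pons,11528,11684,0.940,2.354,1.014
HC27,pons,10665,11088,0.935,1.266,1.040
HC28,pons,8818,9172,0.954,1.09,1.040
HC29,pons,11251,11716,0.945,1.09,1.041
HC30,pons,11283,11868,0.955,1.699,1.052
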