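id,structure,manual_volume,labs_volume,dice,hausdorff,volume_ratio
012_S_0689,midbrain,5655,5688,0.839,2.685,1.006
033_S_0733,midbrain,4750,3938,0.782,2.442,0.829
136_S_0300,midbrain,5393,5420,0.9,1.2,1.005
027_S_1081,midbrain,3072,3044,0.82,1.72,0.991
032_S_1101,midbrain,4402,4509,0.92,1.168,1.024
033_S_0724,midbrain,3840,3300,0.860,2.411,0.859
131_S_0457,midbrain,3371,3306,0.82,0.801,0.981
127_S_0844,midbrain,3689,3839,0.873,1.628,1.041
133_S_1170,midbrain,3880,3092,0.822,2.1,0.797
136_S_0426,midbrain,4577,4305,0.921,0.91,0.941
012_S_0689,pons,10127,10171,0.949,0.691,1.004
033_S_0733,pons,10733,10618,0.95,0.530,0.989
136_S_0300,pons,9343,8838,0.929,2.160,0.945
027_S_1081,pons,8855,8168,0.914,1.060,0.922
032_S_1101,pons,7967,8220,0.88,1.221,1.031
033_S_0724,pons,7079,6890,0.938,0.785,0.973
131_S_0457,pons,8862,8785,0.96,0.822,0.991
127_S_0844,pons,6902,6013,0.921,1.303,0.871
133_S_1170,pons,9716,9608,0.924,1.177,0.988
136_S_0426,pons,11065,10745,0.96,0.971,0.971
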