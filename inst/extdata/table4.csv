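id,structure,manual_volume,labs_volume,dice,hausdorff,volume_ratio
012_S_0689,midbrain,5420,5688,0.839,4.1193,1.0494
033_S_0733,midbrain,4609,3938,0.793,2.67,0.854
136_S_0300,midbrain,4800,5420,0.934,0.9821,1.129
027_S_1081,midbrain,3342,3044,0.897,1.98,0.91
032_S_1101,midbrain,4585,4509,0.93,1.628,0.983
033_S_0724,midbrain,4018,3300,0.866,1.9878,0.821
131_S_0457,midbrain,3678,3306,0.897,1.6393,0.898
127_S_0844,midbrain,3541,3839,0.93,2.5216,1.084
133_S_1170,midbrain,3800,3092,0.833,2.12,0.813
136_S_0426,midbrain,4623,4305,0.919,1.8703,0.931
012_S_0689,pons,10826,10171,0.952,1.337,0.939
033_S_0733,pons,10567,10618,0.958,1.1847,1.004
136_S_0300,pons,8394,8838,0.959,2.4965,1.052
027_S_1081,pons,9371,8168,0.904,1.578,0.871
032_S_1101,pons,8900,8220,0.950,1.264,0.923
033_S_0724,pons,7544,6890,0.948,0.7166,0.913
131_S_0457,pons,8484,8785,0.960,0.7282,1.035
127_S_0844,pons,6076,6013,0.961,1.2825,0.989
133_S_1170,pons,8398,9608,0.922,1.088,1.144
136_S_0426,pons,10904,10745,0.95,1.618,0.985
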