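case,volume_manual_mm3,volume_auto_mm3,voxels_manual,voxels_auto,dsc_percent
1,20820.8,41692.1,682256,1366168,61.79
2,13670.3,16487.9,447949,540277,62.57
3,29006,31706.7,1419342,1551511,84.79
4,51418.2,56490.6,1684871,1851084,88.79
5,44258.4,40306,2165709,1972307,89.42
6,66161.6,67559.2,2167986,2213781,88.76
7,15317.8,13312.5,501932,436224,83.93
8,32826.1,38079.4,1075646,1247786,75
9,22047.6,13289.7,722456,435477,69.68
10,17718.1,16886,866648,825950,84.71
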