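patient,session,n,slope,rmse_without,r2_without,rmse_with,r2_with,z_observed
1,HD1,9,0.632,0.0144,0.906,0.0053,0.985,-1.65
1,HD2,9,0.436,0.0044,0.965,0.0028,0.998,-2.61
2,HD1,9,0.000,0.0417,0.847,0.0417,0.847,0.00
2,HD2,8,0.000,0.0029,0.999,0.0029,0.999,0.00
3,HD1,9,0.280,0.0071,0.958,0.0037,0.987,-1.05
3,HD2,9,0.115,0.0041,0.978,0.0038,0.981,-0.12
4,HD1,9,0.216,0.0086,0.968,0.0055,0.986,-0.72
4,HD2,9,0.161,0.0051,0.990,0.0018,0.999,-1.74
5,HD1,10,0.310,0.0202,0.820,0.0157,0.870,-0.34
5,HD2,10,0.201,0.0087,0.983,0.0030,0.998,-2.03
6,HD1,9,0.000,0.0016,0.999,0.0016,0.999,0.00
6,HD2,9,0.011,0.0048,0.994,0.0047,0.994,-0.00
7,HD1,9,0.395,0.0114,0.931,0.0037,0.993,-1.96
7,HD2,9,0.221,0.0085,0.976,0.0052,0.991,-0.85
8,HD1,9,0.000,0.0053,0.992,0.0053,0.992,0.00
8,HD2,9,0.127,0.0077,0.983,0.0065,0.988,-0.27
9,HD1,7,0.000,0.0091,0.987,0.0091,0.987,0.00
9,HD2,7,0.180,0.0057,0.996,0.0033,0.999,-0.77
10,HD1,9,0.156,0.0087,0.982,0.0068,0.989,-0.43
10,HD2,9,0.128,0.0049,0.994,0.0037,0.997,-0.50
11,HD1,9,0.057,0.0037,0.997,0.0032,0.998,-0.28
11,HD2,9,0.000,0.0031,0.998,0.0031,0.998,0.00
12,HD1,9,0.079,0.0032,0.997,0.0021,0.999,-0.71
12,HD2,9,0.000,0.0055,0.993,0.0055,0.993,0.00
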