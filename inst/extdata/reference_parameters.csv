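patient,session,slope,V1,V2,V3,kd,k1,k2
1,HD1,0.632,2.82,8.46,22.57,10.12,233.80,20.88
1,HD2,0.436,2.82,8.46,22.57,9.43,34.15,719.13
2,HD1,0.000,2.72,8.16,21.75,6.77,5.29,705.20
2,HD2,0.000,2.72,8.16,21.75,7.37,44.37,5.90
3,HD1,0.290,3.02,9.07,24.19,8.88,29.13,10.46
3,HD2,0.115,3.02,9.07,24.19,7.38,15.60,5.98
4,HD1,0.216,3.62,10.85,28.93,9.33,318.36,13.68
4,HD2,0.161,3.62,10.85,28.93,8.07,69.83,9.24
5,HD1,0.310,3.45,10.34,27.57,9.80,22.67,834.39
5,HD2,0.201,3.45,10.34,27.57,8.08,145.95,5.16
6,HD1,0.000,2.81,8.44,22.51,9.23,21.50,9.23
6,HD2,0.011,2.81,8.44,22.51,9.90,20.31,6.39
7,HD1,0.395,4.36,13.07,34.86,6.63,220.76,8.75
7,HD2,0.221,4.36,13.07,34.86,9.12,59.11,8.78
8,HD1,0.000,3.60,10.79,28.77,8.99,21.56,7.42
8,HD2,0.127,3.60,10.79,28.77,9.71,45.40,8.08
9,HD1,0.000,3.87,11.62,30.99,11.26,70.34,14.84
9,HD2,0.180,3.87,11.62,30.99,8.88,57.68,4.89
10,HD1,0.156,3.69,11.07,29.51,8.27,142.39,5.94
10,HD2,0.128,3.69,11.07,29.51,6.56,32.15,3.65
11,HD1,0.057,2.45,7.35,19.61,6.48,19.22,5.30
11,HD2,0.000,2.45,7.35,19.61,8.42,29.27,10.99
12,HD1,0.079,3.69,11.07,29.51,8.72,177.57,6.16
12,HD2,0.000,3.69,11.07,29.51,11.11,325.43,11.81
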