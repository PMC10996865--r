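patient,duration_hd1_min,duration_hd2_min,hd1_without,hd1_with,hd2_without,hd2_with
1,240,240,19.84,23.03,20.88,23.79
2,240,230,24.69,26.35,18.17,24.49
3,240,240,12.67,14.68,10.25,9.57
4,240,240,26.49,27.98,28.86,25.87
5,270,270,24.33,28.16,33.07,30.63
6,240,240,21.18,21.18,21.97,21.22
7,240,240,23.55,25.11,25.13,31.10
8,240,240,25.11,25.34,25.11,28.51
9,180,180,39.38,39.38,42.20,32.28
10,240,240,28.44,29.87,28.27,23.47
11,240,240,21.83,22.19,20.07,26.29
12,240,240,25.06,25.79,26.43,34.17
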