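sample,amplitude_px,wavelength_frames,count
1,5.47,25.17,18
2,7.00,23.29,24
3,7.54,22.73,26
4,5.39,22.86,28
5,5.38,22.27,26
6,6.07,20.03,32
7,5.09,24.94,18
8,7.43,23.86,21
9,6.98,24.37,19
10,5.71,22.61,18
11,6.65,22.05,21
12,9.07,20.67,15
13,6.08,19.11,35
14,4.54,17.00,32
15,3.80,21.56,25
16,7.51,21.45,29
17,7.37,20.00,26
18,7.96,22.24,29
19,6.94,19.08,24
20,6.62,17.96,27
21,8.52,15.19,32
22,7.19,15.55,29
23,4.79,20.64,22
24,8.29,21.33,21
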