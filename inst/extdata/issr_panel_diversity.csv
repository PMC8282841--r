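primer,na,ne,h,i,tsb,pb,ppb,nm
ISSR 11,1.95,1.43,0.275,0.431,19,18,94.74,1.48
ISSR 18,1.94,1.30,0.208,0.343,18,17,94.44,1.85
UBC 807,2.00,1.35,0.226,0.367,17,17,100,2.51
UBC 808,2.00,1.43,0.276,0.435,16,16,100,2.45
UBC 809,2.00,1.26,0.200,0.345,22,22,100,2.74
UBC 810,1.84,1.31,0.206,0.331,13,11,84.62,2.83
UBC 816,2.00,1.28,0.197,0.335,22,22,100,2.96
UBC 836,2.00,1.48,0.306,0.475,22,22,100,2.93
UBC 841,1.94,1.33,0.228,0.369,19,18,94.74,2.18
UBC 844,2.00,1.35,0.245,0.398,19,19,100,2.27
UBC-815,2.00,1.27,0.186,0.312,19,19,100,1.85
UBC 817,2.00,1.28,0.203,0.343,17,17,100,2.65
UBC 873,2.00,1.43,0.283,0.447,13,13,100,1.92
ISSR 811,2.00,1.59,0.357,0.536,12,12,100,0.47
ISSR 901,1.91,1.36,0.238,0.379,12,11,91.67,1.59
UBC 835a,2.00,1.27,0.178,0.299,17,17,100,2.14
ISSR 889,2.00,1.40,0.244,0.382,15,15,100,2.42
ISSR 812,2.00,1.41,0.245,0.382,15,15,100,2.40
ISSR 842,2.00,1.50,0.301,0.457,11,11,100,1.93
A-856,1.92,1.32,0.215,0.351,14,13,92.86,3.07
I-825,1.93,1.29,0.189,0.311,16,15,93.75,2.96
ISSR 10,2.00,1.56,0.321,0.483,12,12,100,1.86
ISSR 17,1.93,1.40,0.259,0.412,15,14,93.33,1.85
Primer 9,2.00,1.49,0.296,0.457,12,12,100,1.29
ISSR 856,2.00,1.32,0.218,0.360,18,18,100,2.98
ISSR 2M,2.00,1.42,0.274,0.434,15,15,100,2.69
UBC 835b,1.94,1.38,0.258,0.410,17,16,94.12,2.54
UBC 813,2.00,1.40,0.276,0.442,17,17,100,2.11
Primer 3,1.92,1.38,0.246,0.390,14,13,92.86,2.68
ISSR 848,2.00,1.50,0.326,0.495,15,15,100,1.41
UBC 825,2.00,1.42,0.259,0.4037,13,13,100,2.83
UBC 830,1.92,1.32,0.209,0.338,14,13,92.86,2.36
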