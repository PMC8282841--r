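primer,tsb,pb,h,pic,emr,havp,mi,d,rp
ISSR 11,19,18,0.304,0.257,3.545,0.0004,0.9129,0.965,7.091
ISSR 18,18,17,0.230,0.204,2.386,0.0003,0.4857,0.983,4.773
UBC 807,17,17,0.266,0.230,2.682,0.0004,0.6180,0.975,5.364
UBC 808,16,16,0.301,0.256,2.955,0.0004,0.7557,0.966,5.909
UBC 809,22,22,0.206,0.185,2.568,0.0002,0.4750,0.986,5.136
UBC 810,13,11,0.251,0.219,1.909,0.0004,0.4184,0.979,3.636
UBC 816,22,22,0.222,0.197,2.795,0.0002,0.5514,0.984,5.591
UBC 836,22,22,0.333,0.277,4.636,0.0003,1.2858,0.956,9.273
UBC 841,19,18,0.251,0.219,2.795,0.0003,0.6135,0.979,5.591
UBC 844,19,19,0.259,0.226,2.909,0.0003,0.6566,0.977,5.818
UBC-815,19,19,0.212,0.190,2.295,0.0003,0.4358,0.986,4.591
UBC 817,17,17,0.218,0.194,2.114,0.0003,0.4101,0.985,4.227
UBC 873,13,13,0.306,0.259,2.455,0.0005,0.6367,0.965,4.909
ISSR 811,12,12,0.390,0.314,3.182,0.0007,0.9983,0.930,6.182
ISSR 901,12,11,0.268,0.232,1.909,0.0005,0.4425,0.975,3.818
UBC 835a,17,17,0.216,0.192,2.091,0.0003,0.4024,0.985,4.182
ISSR 889,15,15,0.288,0.246,2.614,0.0004,0.6439,0.970,5.227
ISSR 812,15,15,0.313,0.264,2.909,0.0005,0.7674,0.963,5.818
ISSR 842,11,11,0.457,0.353,3.886,0.0009,1.3702,0.876,4.773
A-856,14,13,0.243,0.213,1.977,0.0004,0.4215,0.980,3.955
I-825,16,15,0.244,0.214,2.273,0.0003,0.4864,0.980,4.273
ISSR 10,12,12,0.369,0.301,2.932,0.0007,0.8827,0.941,5.864
ISSR 17,15,14,0.298,0.253,2.727,0.0005,0.6907,0.967,5.364
Primer 9,12,12,0.339,0.281,2.591,0.0006,0.7287,0.954,5.182
ISSR 856,18,18,0.250,0.219,2.636,0.0003,0.5768,0.979,5.273
ISSR 2M,15,15,0.307,0.260,2.841,0.0005,0.7384,0.964,5.682
UBC 835b,17,16,0.280,0.241,2.864,0.0004,0.6899,0.972,5.727
UBC 813,17,17,0.285,0.245,2.932,0.0004,0.7174,0.970,5.864
Primer 3,14,13,0.276,0.238,2.318,0.0004,0.5521,0.973,4.636
ISSR 848,15,15,0.375,0.305,3.750,0.0006,1.1426,0.938,7.227
UBC 825,13,13,0.317,0.267,2.568,0.0006,0.6852,0.961,4.864
UBC 830,14,13,0.243,0.213,1.977,0.0004,0.4215,0.980,3.955
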