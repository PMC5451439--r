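mouse,section,slice,D_um2_per_h,rho_per_h,velocity_um_per_h,error_E2
1,transverse,1,463.09,0.027164,3.6967,103.23
1,transverse,2,554.98,0.02052,3.4259,99.92
1,transverse,3,3074.8,0.015377,5.4098,80.24
1,transverse,4,2923.1,0.010395,3.8589,82.02
1,sagittal,1,305.51,0.0063098,1.2091,127.85
1,sagittal,2,626.77,0.0011284,0.3342,119.51
1,coronal,1,91.762,0.10424,2.8026,94.81
1,coronal,2,336.48,0.034115,2.7293,91.14
2,transverse,1,534.97,0.017231,3.0134,75.99
2,transverse,2,2955.1,0.011975,4.0672,71.22
2,transverse,3,3171.1,0.01068,3.7663,74.35
2,transverse,4,3261.4,0.0074994,2.8306,73.75
2,transverse,5,598.27,0.0084187,1.4412,67.44
2,transverse,6,558.54,0.009343,1.3758,64.72
2,transverse,7,1284.4,0.000037942,2.2519,71.19
2,transverse,8,530.47,0.013664,2.21,68.79
2,sagittal,1,10984,0.0080234,4.2752,91.78
2,sagittal,2,1656.4,0.0037629,1.6703,87.20
2,sagittal,3,837.34,0.0070626,1.9906,73.21
2,sagittal,4,3098.5,0.0050553,2.2666,78.46
2,sagittal,5,83.08,0.070895,2.5196,107.28
2,sagittal,6,5250,0.015,2.7293,115.82
2,sagittal,7,111.77,0.11002,3.7248,105.85
2,coronal,1,8317.9,0.004686,1.9781,84.79
2,coronal,2,11120,0.007827,4.0281,79.72
2,coronal,3,370.53,0.031518,3.6641,97.47
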