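mouse,hypothesis,interval_start,interval_end,D_um2_per_h,rho_per_h,velocity_um_per_h,error,error_mode
1,1,11,25,413.77,0.0188,5.5781,0.4524,mean
1,2,11,15,139.24,0.0182,3.1838,0.1196,per_interval
1,2,15,18,839.93,0.0248,9.1280,0.1191,per_interval
1,2,18,22,1047.6,0.0192,8.9697,0.1029,per_interval
1,2,22,25,968.75,0.0082,5.6369,0.0949,per_interval
1,3,11,15,139.24,0.0182,3.1838,0.1196,per_interval
1,3,15,18,233.97,0.0499,6.8338,0.1145,per_interval
1,3,18,22,1156.2,0.0178,9.0731,0.0688,per_interval
1,3,22,25,1305.6,0.0105,7.4051,0.0644,per_interval
2,1,11,25,319.22,0.0167,4.6178,0.4528,mean
2,2,11,15,558.74,0.0235,7.2472,0.1151,per_interval
2,2,15,18,206.21,0.0100,2.8720,0.1067,per_interval
2,2,18,22,346.35,0.0055,2.7604,0.1042,per_interval
2,2,22,25,886.07,0.0104,6.0713,0.0979,per_interval
2,3,11,15,558.74,0.0235,7.2472,0.1151,per_interval
2,3,15,18,950.79,0.0051,4.4041,0.0846,per_interval
2,3,18,22,77.734,0.0369,3.3873,0.0621,per_interval
2,3,22,25,94.161,0.0520,4.4255,0.0643,per_interval
3,1,18,25,651.17,0.0177,6.7899,0.2833,mean
3,2,18,22,859.70,0.0127,6.6085,0.1408,per_interval
3,2,22,25,454.29,0.0236,6.5487,0.1364,per_interval
3,3,18,22,859.704,0.0127,6.6085,0.1408,per_interval
3,3,22,25,1552.1,0.0200,11.1431,0.1027,per_interval
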