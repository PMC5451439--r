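mouse,day,volume_mm3
1,11,0.715
1,15,1.155
1,18,4.980
1,22,15.570
1,25,25.460
2,11,0.595
2,15,3.025
2,18,4.320
2,22,8.095
2,25,12.340
3,11,0.970
3,15,3.855
3,18,16.485
3,22,30.675
3,25,61.490
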