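initial_density_percent,D_um2_per_h,rho_per_h,velocity_um_per_h,error
30,316.43,0.0226,5.3484,0.4510
50,413.77,0.0188,5.5781,0.4524
70,441.52,0.0168,5.4476,0.4592
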