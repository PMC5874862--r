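r_cm,hd810,mcnp,flexisource,mhdr_v2r,gammamed_12i
1.0,1,1.0000,1.000,1.0000,1.000
1.5,1.0097,1.0027,1.002,1.0028,1.004
2.0,1.0147,1.0044,1.004,1.0050,1.006
2.5,1.0203,1.0054,,1.0066,
3.0,1.0211,1.0050,1.005,1.0075,1.008
3.5,1.0195,,,1.0076,
4.0,1.0174,1.0019,1.003,1.0067,1.005
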