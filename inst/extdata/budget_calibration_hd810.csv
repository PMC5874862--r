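label,kind,value_pct
Film uniformity,B,3
Scanner consistency,A,1
Fitted dose value process,B,1.5
Calibration film dose value (beam flatness),B,1.8
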