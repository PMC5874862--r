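label,kind,value_pct
Phantom full scatter (deviation from unbounded),A,0.5
Repeatability of film scanning,A,0.3
Distance between source center and film emulsion,B,0.1
Source strength,B,2
Exposure time,B,0.02
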