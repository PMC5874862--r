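source,active_length_mm,total_length_mm,active_core_diameter_mm,external_diameter_mm,capsule_thickness_mm,distal_capsule_thickness_mm
mHDR-v2r,3.5,4.95,0.60,0.90,0.100,0.20
Flexisource,3.5,4.60,0.60,0.85,0.090,0.65
GammaMed HDR 12i,3.5,4.96,0.60,1.10,0.200,0.96
BEBIG GI192M11,3.5,4.90,0.60,1.00,0.200,0.84
Generic,3.5,5.00,0.60,1.00,0.200,0.60
IRAsource,3.5,4.30,0.60,0.90,0.150,0.25
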