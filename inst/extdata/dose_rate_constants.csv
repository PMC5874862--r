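source,method,lambda_cGy_per_hU,uncertainty_k1
mHDR-v2r,PENELOPE,1.112,0.0004
Flexisource,GEANT4,1.109,0.011
GammaMed HDR 12i,GEANT3,1.108,0.003
BEBIG GI192M11,GEANT4,1.117,0.003
IRAsource,MCNP4C,1.112,0.008
IRAsource,HD-810 film,1.129,0.044
IRAsource,EBT film,1.084,0.046
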