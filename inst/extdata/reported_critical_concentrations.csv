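name,cvc_reported_wtpct,cfc_reported_wtpct
guar_gum,0.11,0.037
BG1,0.18,0.040
BG2,0.24,0.044
BG3,0.38,0.042
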