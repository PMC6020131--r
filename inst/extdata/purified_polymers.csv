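name,mw_kg_per_mol,rh_nm,purity
guar_gum,2490,78,0.871
BG1,1020,51,0.901
BG2,650,38,0.910
BG3,272,23,0.938
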