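# gradual epithelial death with fibroblast proliferation
molecular.k_synL = 1.5e-6
agents.V_ePGE2 = 1.5e-12
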