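# excessive proliferation and differentiation
agents.V_ePGE2 = 1.5e-13
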