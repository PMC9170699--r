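"energy_keV","weight"
30,0.25
60,0.5
120,0.25
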