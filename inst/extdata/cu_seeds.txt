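# Cu family seed sunids (synthetic fixture)
10023
10028
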