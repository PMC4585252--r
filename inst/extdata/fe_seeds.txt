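# Fe family seed sunids (synthetic fixture)
10004
10009
10016
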