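stim   111000111100111000
avatar 100000111000000000
static 011000101100000000
shadow 000000000000111000
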