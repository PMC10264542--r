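pH,C0,CD_t,CA_t
7.4,3700.9,3247.7,675.5
8.0,3696.3,3296.8,329.9
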