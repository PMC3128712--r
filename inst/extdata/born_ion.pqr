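ATOM      1 ION  BRN     1      0.0000   0.0000   0.0000   1.0000   2.0000
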