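b0001
b0002
b0003
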