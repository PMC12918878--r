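regulator	mode	targets
b0004	activator	b0005,b0006
b0007	repressor	b0008,b0009,b0010
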