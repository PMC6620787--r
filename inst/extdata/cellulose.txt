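# cellulose
3.2.1.4
3.2.1.21
3.2.1.91
3.2.1.74
3.2.1.176
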