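# starch_glucose
3.2.1.20
3.2.1.1
3.2.1.3
3.2.1.2
3.2.1.10
3.2.1.41
3.2.1.68
3.2.1.133
2.4.1.1
2.4.1.25
5.4.99.16
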