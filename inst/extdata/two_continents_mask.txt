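1111111111110111111111111
1111111111110111111111111
1111111111110111111111111
1111111111110111111111111
1111111111110111111111111
1111111111111111111111111
1111111111110111111111111
1111111111110111111111111
1111111111110111111111111
1111111111110111111111111
1111111111110111111111111
1111111111110111111111111
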