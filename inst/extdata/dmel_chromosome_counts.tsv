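chromosome	count
2R	114
3L	106
3R	106
2L	57
X	49
4	20
Y	17
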