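5
7
8
9
23
25
38
60
61
62
65
66
68
73
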