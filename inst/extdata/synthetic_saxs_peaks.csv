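"sample","q"
"F1",0.108384
"F1",0.125152
"F2",0.113166
"F2",0.130673
"F3",0.111526
"F3",0.128779
"F4",0.114855
"F4",0.132623
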