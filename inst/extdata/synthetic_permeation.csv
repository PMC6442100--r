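"label","time_h","conc_ug_ml"
"cubic",0.5,19.6588
"cubic",1,67.2553
"cubic",2,156.975
"cubic",3,239.0295
"cubic",4,320.7126
"cubic",5,380.5694
"solution",0.5,21.735
"solution",1,57.5179
"solution",2,123.31
"solution",3,183.8824
"solution",4,235.764
"solution",5,289.2617
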