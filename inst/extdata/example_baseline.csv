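"age","female","male"
30,2e-04,2e-04
40,0.001,0.001
50,0.004,0.005
60,0.01,0.012
70,0.02,0.024
80,0.032,0.038
94,0.041,0.049
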