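TrackID,Time,Position X,Position Y,Position Z
1000000001,0,54.21,31.08,12.50
1000000001,0.5,54.64,31.55,12.81
1000000001,1,55.02,32.13,13.04
1000000001,1.5,55.60,32.40,13.47
1000000002,0,70.15,48.92,20.11
1000000002,0.5,69.88,48.55,19.73
1000000002,1,69.31,48.02,19.38
1000000002,1.5,68.94,47.66,18.95
1000000003,0.5,12.04,87.33,5.06
1000000003,1,12.60,87.91,5.62
1000000003,1.5,13.11,88.47,6.30
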