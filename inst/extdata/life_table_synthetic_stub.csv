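"age","q","ex"
18,0.00070822,48.36
20,0.000847834,46.43
25,0.00132935,41.66
30,0.00208404,36.97
35,0.0032665,32.41
40,0.00511813,28
45,0.00801514,23.8
50,0.0125416,19.85
55,0.0195989,16.21
60,0.0305655,12.93
65,0.0475181,10.06
70,0.0735099,7.62
75,0.112852,5.62
80,0.171216,4.04
85,0.255112,2.84
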