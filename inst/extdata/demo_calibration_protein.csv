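conc_uM,a562
10,0.27900000000000003
20,0.55800000000000005
30,0.83700000000000008
40,1.1160000000000001
50,1.395
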