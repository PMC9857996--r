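time_min,value
0,0
2.5,0.051263903313606425
5,0.08610288298379544
7.5,0.1097794746205015
10,0.12587010060433357
12.5,0.13680529974634956
15,0.14423686769129468
17.5,0.14928736575750129
20,0.15271968729526056
22.5,0.1550522950864392
25,0.15663753675089567
27.5,0.15771486794400594
30,0.15844702287386406
32.5,0.15894459580662954
35,0.15928274667241529
37.5,0.15951255420514446
40,0.15966873154325756
42.5,0.15977486975661565
45,0.15984700135055205
47.5,0.15989602202537961
50,0.15992933650561514
52.5,0.15995197704651481
55,0.1599673635717917
57.5,0.15997782026366777
60,0.15998492663778563
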