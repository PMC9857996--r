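ligand_total,intensity
0,100
1,96.694267635777024
2,93.413954690096901
3,90.161922157165279
4,86.941408425945809
5,83.756077275301038
6,80.610068379015473
7,77.508048275314792
8,74.455258459170125
9,71.457555511280205
10,68.521435968756364
11,65.654036071642679
12,62.863093905215067
13,60.156859451353995
14,57.543937733432728
14.999999999999998,55.033053037404159
16,52.632729631455845
17,50.350897356430075
18,48.194448098036844
18.999999999999996,46.168788040711135
20,44.277444722606205
21,42.521790450196676
22,40.900930336822675
23,39.411775591707013
24,38.049288488162958
24.999999999999996,36.806855585175818
26,35.676729088181688
27,34.650475616657701
28,33.719383850385128
29,32.874800973643701
29.999999999999996,32.108386125227241
31,31.412283152307452
32,30.779223541348642
32.999999999999993,30.202574063160796
34,29.676343872848832
35,29.195164050312869
36,28.75425001389425
37,28.349354623634042
37.999999999999993,27.976717490809278
39,27.633014166125321
40,27.315307492363289
41,27.021002416587379
42,26.747804880386866
42.999999999999993,26.493684964996277
44,26.256844194763161
44.999999999999993,26.035686745170935
46,25.828794221785913
47,25.63490364645962
48,25.452888287740905
49,25.281740990850594
49.999999999999993,25.12055969027756
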