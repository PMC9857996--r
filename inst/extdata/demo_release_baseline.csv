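time_min,value
0,0
2.5,0.22461354302795772
5,0.40573463458042219
7.5,0.55178482088229164
10,0.66955496424868166
12.5,0.76452099626642045
15,0.8410985309403568
17.5,0.90284817649406979
20,0.95264109216111026
22.5,0.99279248782326623
25,1.0251692737981857
27.5,1.0512768661440668
30,1.0723291836479321
32.5,1.0893050911315454
35,1.1029939135065301
37.5,1.1140321368353718
40,1.122933002879192
42.5,1.1301103731832538
45,1.1358979723031615
47.5,1.1405649049196658
50,1.1443281683378372
52.5,1.1473627421614374
55,1.14980972427978
57.5,1.1517828914642199
60,1.1533739896208293
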