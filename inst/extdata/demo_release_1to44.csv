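time_min,value
0,0
2.5,0.092808999705336653
5,0.17276201369977007
7.5,0.24163986463114359
10,0.30097669400013788
12.5,0.35209413265357609
15,0.39613073795041043
17.5,0.43406735326512857
20,0.4667489546700479
22.5,0.49490347139562541
25,0.51915799926375805
27.5,0.54005276822179127
30,0.55805317508121388
32.5,0.57356014947061829
35,0.58691908388757974
37.5,0.59842752675175392
40,0.6083418098093758
42.5,0.61688275750375376
45,0.6242406054786529
47.5,0.63057923776618741
50,0.63603983703565314
52.5,0.64074402920662521
55,0.64479659246743359
57.5,0.64828779103797607
60,0.65129538565761591
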