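time_min,value
0,0
2.5,0.2026523057824893
5,0.35522173712722305
7.5,0.47008562328423292
10,0.55656239800117535
12.5,0.62166756565345771
15,0.67068284020441016
17.5,0.70758462889400608
20,0.73536662177208389
22.5,0.756282657435558
25,0.77202956766606634
27.5,0.78388483440003531
30,0.7928102265738759
32.5,0.79952982447449483
35,0.80458876138914837
37.5,0.80839744802262792
40,0.81126486742650061
42.5,0.81342364152081192
45,0.81504890275186037
47.5,0.81627250186587119
50,0.8171937044167018
52.5,0.81788724377116839
55,0.81840938391913065
57.5,0.81880248393913413
60,0.81909843441589758
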