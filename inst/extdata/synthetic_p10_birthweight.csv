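ga_week,p10_g
24,520
26,720
28,1000
30,1260
32,1560
34,1900
35,2100
36,2300
37,2550
38,2750
39,2900
40,3000
41,3090
42,3150
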