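week,p10_g,p90_g
32,1500,2600
33,1700,2900
34,1900,3100
35,2100,3300
36,2300,3500
37,2500,3700
38,2600,3900
39,2750,4000
40,2850,4100
41,2900,4200
42,2950,4250
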