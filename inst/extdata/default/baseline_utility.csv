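# provenance: placeholder
age,utility
60,0.8
61,0.8
62,0.8
63,0.8
64,0.8
65,0.8
66,0.8
67,0.8
68,0.8
69,0.8
70,0.8
71,0.8
72,0.8
73,0.8
74,0.8
75,0.8
76,0.8
77,0.8
78,0.8
79,0.79375
80,0.7875
81,0.78125
82,0.775
83,0.76875
84,0.7625
85,0.75625
86,0.75
87,0.74375
88,0.7375
89,0.73125
90,0.725
91,0.71875
92,0.7125
93,0.70625
94,0.7
95,0.69375
96,0.6875
97,0.68125
98,0.675
99,0.66875
100,0.6625
101,0.65625
102,0.65
103,0.64375
104,0.6375
105,0.63125
106,0.625
107,0.61875
108,0.6125
109,0.60625
110,0.6
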