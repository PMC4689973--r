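# provenance: placeholder
age,qx
60,0.00873024402883438
61,0.00957105845482864
62,0.0104994724799432
63,0.0115245163059702
64,0.0126561297248711
65,0.0139052490131265
66,0.015283901063695
67,0.0168053051097392
68,0.0184839823461913
69,0.0203358736848351
70,0.0223784657802681
71,0.02463092533113
72,0.0271142414853163
73,0.0298513759499975
74,0.032867420115923
75,0.0361897581376207
76,0.0398482344515778
77,0.0438753236459987
78,0.0483062998987692
79,0.0531794023531473
80,0.0585359917798676
81,0.0644206926548893
82,0.0708815133385062
83,0.077969935349568
84,0.0857409607667995
85,0.0942531045425029
86,0.10356831597759
87,0.113751810792499
88,0.12487179217161
89,0.136999035928708
90,0.15020631165368
91,0.164567608533651
92,0.180157131752815
93,0.197048033323057
94,0.215310840363864
95,0.235011544862677
96,0.256209322597174
97,0.278953856155175
98,0.303282248979907
99,0.329215535368007
100,0.356754816686757
101,0.385877088018284
102,0.41653086296721
103,0.448631757886712
104,0.482058259688406
105,0.516647971575616
106,0.552194704196341
107,0.588446848767066
108,0.625107523225527
109,0.661837008356386
110,1
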