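patient_id,entry,exit,event,x1,x2
1,0,1.5358,1,1.163,0
2,0,3.3388,0,-0.586,0
3,0,0.1025,1,1.785,0
4,0,1.297,1,-1.333,0
5,0,3.1504,0,-0.447,1
6,0,0.497,1,0.57,0
7,0,0.621,0,-2.89,1
8,0,3.5247,0,-0.869,1
9,0,3.7804,1,-0.462,0
10,0,1.0961,1,-0.556,1
11,0,0.938,1,-0.02,0
12,0,2.0216,1,-0.15,0
13,0,0.3877,1,-0.628,0
14,0,0.9456,1,1.323,1
15,0,3.1066,0,-1.521,0
16,0,3.1862,0,-0.437,0
17,0,2.9813,1,0.971,0
18,0,0.1484,1,0.028,0
19,0,1.1998,0,-0.086,0
20,0,1.3274,1,0.389,0
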