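id,sex,age,gfr,mtv,pct_id
1,M,74,66,161,0.2
2,F,67,78,1371,1.8
3,M,72,64,3077,3.4
4,F,78,40,104,0.1
5,F,54,95,1815,2.6
6,F,68,100,1899,27.2
7,M,68,54,1121,1.4
8,F,63,77,246,0.5
9,M,71,67,1686,20.8
10,F,79,69,732,2.1
11,M,24,98,1041,1.6
12,F,51,89,14002,24.4
13,M,79,83,12448,18.6
14,M,60,100,8,0.1
15,F,65,68,342,0.6
16,M,70,95,8574,10.2
17,M,79,85,809,1.0
18,M,61,70,2475,2.2
19,F,55,59,873,1.1
20,M,81,85,1691,2.8
21,M,51,109,17228,25.5
22,F,65,66,1836,2.9
23,M,78,59,2764,4.6
24,F,21,139,550,0.9
25,F,77,70,280,0.5
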