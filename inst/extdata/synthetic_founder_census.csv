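t,c1,c2,c3,c4
0,500,0,0,0
1,475,4,1,3
2,450,7,4,5
3,432,12,6,5
4,419,10,8,7
5,411,8,8,9
6,379,13,6,15
7,362,13,6,18
8,352,10,8,19
9,341,9,10,19
10,324,9,9,22
11,303,10,8,25
12,289,11,6,27
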