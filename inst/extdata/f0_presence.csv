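individual,typed,A01a,A01b,A02,A03,A04,A05,A06,A07,B01,B03,B04,B05,B06,B09,B10,B11,B12,B13,B17,B18,C01
1,complete,0,0,0,0,0,0,0,0,0,0,0,0,0,1,1,1,1,0,0,0,0
2,complete,0,0,0,0,0,0,0,0,0,0,0,0,0,1,1,1,1,0,0,0,0
3,complete,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,1,0,0,0,0,0
4,complete,1,0,0,1,0,0,0,0,0,0,0,0,0,0,1,1,0,0,0,0,0
5,complete,0,1,0,1,0,0,0,0,0,0,0,0,0,1,0,0,1,0,0,0,0
6,complete,1,0,1,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
7,complete,1,0,0,1,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0
8,complete,0,0,0,0,0,0,1,1,0,0,0,0,1,0,0,0,0,0,0,0,0
9,complete,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,1,1,0
10,complete,0,0,0,0,0,0,0,0,1,0,0,0,1,0,0,0,0,1,0,0,0
11,complete,0,0,0,0,0,0,0,0,1,0,1,0,0,0,0,0,0,1,0,0,1
12,complete,0,0,0,0,0,1,0,0,1,0,0,0,0,0,0,0,0,1,0,0,0
13,complete,0,0,0,0,0,1,0,0,0,0,1,0,0,0,0,0,0,0,0,0,1
14,complete,0,0,0,0,0,1,0,0,0,0,1,0,0,0,0,0,0,0,0,0,1
15,complete,0,0,0,0,0,1,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0
16,complete,0,0,0,0,0,1,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0
17,complete,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,1
18,complete,1,0,1,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,1
19,complete,0,0,0,0,0,0,0,0,0,1,0,0,1,0,0,0,0,0,0,0,0
20,complete,0,0,0,0,0,0,0,0,0,1,0,1,0,0,0,0,0,0,0,0,0
21,complete,0,0,0,0,1,0,0,0,1,0,0,0,0,0,0,0,0,1,0,0,0
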