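c1,c2,c3,c4,c5,c6,c7,c8,c9
0,0,0,0,0,0,0,0,0
0,10,1,3,2,0,0,0,0
0,7,187,117,48,5,0,0,0
0,3,49,684,412,65,8,0,0
0,1,20,305,1912,456,35,2,0
1,0,4,49,353,653,76,3,0
0,0,1,2,42,121,119,5,0
0,0,0,1,1,22,14,17,0
0,0,0,0,2,0,0,1,0
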