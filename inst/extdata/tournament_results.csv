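score,p1_avatar,p1_shadow,p1_static,p1_none,p2_avatar,p2_shadow,p2_static,p2_none
27,12,0,0,0,15,0,0,0
26,13,0,0,0,13,0,0,0
24,12,1,0,0,13,0,0,0
23,12,0,0,0,11,0,0,0
22,13,0,0,0,9,0,0,0
22,10,0,0,0,12,0,0,0
19,9,1,0,0,11,0,0,0
19,14,0,0,0,8,2,1,0
19,11,1,0,0,10,1,0,0
18,8,0,0,0,12,1,1,0
18,11,0,0,0,10,3,0,0
16,11,1,0,0,8,1,1,0
12,10,2,0,1,6,0,0,1
10,9,0,1,0,6,1,2,1
10,9,1,1,0,3,0,0,0
6,9,2,1,0,6,3,2,1
-1,5,7,1,0,7,5,0,0
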