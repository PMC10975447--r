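sample,particle_size_um,moisture_pct,glidant_coded,type
1,1100.0,3.0,-1.0,granule
2,1100.0,1.0,1.0,granule
3,350.0,3.0,1.0,granule
4,350.0,1.0,-1.0,granule
5,725.0,2.0,0.0,granule
6,194.7,2.0,0.0,granule
7,1255.3,2.0,0.0,granule
8,725.0,0.6,0.0,granule
9,725.0,3.4,0.0,granule
10,725.0,2.0,-1.4,granule
11,725.0,2.0,1.4,granule
12,725.0,2.0,0.0,granule
13,1100.0,3.0,-1.0,pellet
14,1100.0,1.0,1.0,pellet
15,350.0,3.0,1.0,pellet
16,350.0,1.0,-1.0,pellet
17,725.0,2.0,0.0,pellet
18,194.7,2.0,0.0,pellet
19,1255.3,2.0,0.0,pellet
20,725.0,0.6,0.0,pellet
21,725.0,3.4,0.0,pellet
22,725.0,2.0,-1.4,pellet
23,725.0,2.0,1.4,pellet
24,725.0,2.0,0.0,pellet
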