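formulation_id,role,xanthan,guar,hpmc
1,vertex,0.36,0.04,3.60
2,vertex,0.04,0.36,3.60
3,vertex,0.04,0.60,3.36
4,vertex,0.60,0.04,3.36
5,vertex,0.60,0.60,2.80
6,edge-centroid,0.20,0.20,3.60
7,edge-centroid,0.48,0.04,3.48
8,edge-centroid,0.32,0.60,3.08
9,edge-centroid,0.04,0.48,3.48
10,edge-centroid,0.60,0.32,3.08
11,overall-centroid,0.33,0.33,3.34
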