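K	2
mafs	0.2	0.2
prevalence	0.64
heritability	0.4
0,0	0.4865
1,0	0.9601
2,0	0.5377
0,1	0.9473
1,1	0.0042
2,1	0.8113
0,2	0.6401
1,2	0.6065
2,2	0.9089
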