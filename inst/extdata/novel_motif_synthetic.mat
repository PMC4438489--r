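>novel_synthetic
0.100000	0.100000	0.100000	0.700000
0.100000	0.100000	0.700000	0.100000
0.850000	0.050000	0.050000	0.050000
0.050000	0.850000	0.050000	0.050000
0.050000	0.850000	0.050000	0.050000
0.050000	0.050000	0.050000	0.850000
0.050000	0.050000	0.850000	0.050000
0.850000	0.050000	0.050000	0.050000
0.050000	0.050000	0.850000	0.050000
0.050000	0.850000	0.050000	0.050000
0.050000	0.050000	0.850000	0.050000
0.050000	0.850000	0.050000	0.050000
0.850000	0.050000	0.050000	0.050000
0.050000	0.850000	0.050000	0.050000
0.280000	0.240000	0.260000	0.220000
0.050000	0.450000	0.050000	0.450000
0.050000	0.050000	0.850000	0.050000
0.850000	0.050000	0.050000	0.050000
0.050000	0.850000	0.050000	0.050000
0.100000	0.100000	0.100000	0.700000
0.100000	0.100000	0.700000	0.100000
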