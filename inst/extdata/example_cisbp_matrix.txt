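Pos	A	C	G	T
1	0.100000	0.700000	0.100000	0.100000
2	0.050000	0.850000	0.050000	0.050000
3	0.100000	0.100000	0.700000	0.100000
4	0.100000	0.100000	0.700000	0.100000
5	0.800000	0.066000	0.067000	0.067000
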