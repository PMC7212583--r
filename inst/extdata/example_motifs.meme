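MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.25 C 0.25 G 0.25 T 0.25

MOTIF EX1 ets_like
letter-probability matrix: alength= 4 w= 6 nsites= 20 E= 0
0.050000  0.850000  0.050000  0.050000
0.050000  0.850000  0.050000  0.050000
0.100000  0.100000  0.700000  0.100000
0.100000  0.100000  0.700000  0.100000
0.800000  0.066000  0.067000  0.067000
0.800000  0.066000  0.067000  0.067000

MOTIF EX2 at_rich
letter-probability matrix: alength= 4 w= 4 nsites= 20 E= 0
0.700000  0.100000  0.100000  0.100000
0.100000  0.100000  0.100000  0.700000
0.700000  0.100000  0.100000  0.100000
0.100000  0.100000  0.100000  0.700000
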