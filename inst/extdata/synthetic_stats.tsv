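# source_set	synthetic-kd-logistic
# radius	5
# pseudocount	1
# orientation_sign	-1
# version	0.1.0
aa	n_in	n_out	e_star
A	719	281	-0.9373441411
C	780	220	-1.262412448
D	152	848	1.713621265
E	145	855	1.768663754
F	809	191	-1.439538876
G	467	533	0.131927543
H	155	845	1.690663352
I	909	91	-2.291656022
K	121	879	1.975900863
L	872	128	-1.912123151
M	729	271	-0.9872424678
N	151	849	1.721355829
P	319	681	0.756708662
Q	144	856	1.776704176
R	102	898	2.166554046
S	409	591	0.3673494752
T	412	588	0.3549785907
V	879	121	-1.975900863
W	383	617	0.4758459049
Y	352	648	0.6089646598
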