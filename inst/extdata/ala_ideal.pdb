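ATOM      1  N   ALA A   1      -0.966   0.493   1.500  1.00  0.00           N
ATOM      2  CA  ALA A   1       0.257   0.418   0.692  1.00  0.00           C
ATOM      3  C   ALA A   1      -0.094   0.017  -0.716  1.00  0.00           C
ATOM      4  O   ALA A   1      -1.056  -0.682  -0.923  1.00  0.00           O
ATOM      5  CB  ALA A   1       1.204  -0.620   1.296  1.00  0.00           C
TER
END
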