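# Small interaction range: local conformity with global diversity.
A: 1
B: 0.4
S: 0.5
p1: 0.5
p2: 0.5
R: 1
r: 0.01
n_rows: 50
n_cols: 50
T: 100
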