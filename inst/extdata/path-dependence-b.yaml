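# Mirror case: population 2 starts highly committed.
A: 1
B: 0.5
S: 0.5
p1: 0.4
p2: 0.9
R: 10
r: 0.01
n_rows: 50
n_cols: 50
T: 200
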