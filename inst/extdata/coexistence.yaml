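# Benefit of the preferred behavior exceeds the conformity advantage:
# stable coexistence without sanctions.
A: 1
B: 1.2
S: 0.5
p1: 0.5
p2: 0.5
R: 10
r: 0.01
n_rows: 50
n_cols: 50
T: 200
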