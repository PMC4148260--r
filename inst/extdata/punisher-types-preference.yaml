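# Preference-based punishment at L = 1.5; hypocritical punishment
# persists at about (1 - S) * 100% after the norm is established.
A: 1
B: 1.2
S: 0.8
p1: 0.5
p2: 0.5
R: 2
r: 0.01
n_rows: 50
n_cols: 50
T: 400
mode: preference
k: 3
L: 1.5
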