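# Adaptive group pressure: spontaneous norm emergence from coexistence
# (B > A), driven by coincidental local majorities.
A: 1
B: 1.1
S: 0.5
p1: 1
p2: 1
R: 2
r: 0.01
n_rows: 50
n_cols: 50
T: 4000
mode: adaptive
k: 3
C0: 1
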