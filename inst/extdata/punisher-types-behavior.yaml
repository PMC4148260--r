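# Behavior-based punishment at L = 1.5 with a strong majority; sincere
# vs hypocritical sanctions settle near the S : (1 - S) ratio.
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
mode: behavior
k: 3
L: 1.5
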