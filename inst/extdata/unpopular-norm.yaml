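# Highly committed minority (S = 0.8 but p2 >> p1): the minority's
# preferred behavior becomes an unpopular norm.
A: 1
B: 0.5
S: 0.8
p1: 0.25
p2: 0.9
R: 10
r: 0.01
n_rows: 50
n_cols: 50
T: 200
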