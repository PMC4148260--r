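# Persistence: sanctioning strength C0 is reduced at t0 = 1000 after a
# norm has been established; the norm decays only gradually.
A: 1
B: 1.1
S: 0.6
p1: 1
p2: 1
R: 2
r: 0.01
n_rows: 50
n_cols: 50
T: 2000
mode: adaptive
k: 3
C0: 1
schedule:
  - t0: 1000
    param: C0
    value: 0.25
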