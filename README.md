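# normsgame

Stochastic lattice simulator for the **multi-population norms game**: how
does a shared behavioral norm emerge in a society where different groups
hold incompatible preferences — and which behavior wins?

The package is aimed at computational social scientists and evolutionary
game theorists studying norm emergence, costly peer punishment, and
spatial self-organization. It provides the full simulation engine
(compiled inner loop), an analytic mean-field oracle, outcome
classification, phase-diagram sweeps, scheduled interventions, CSV/YAML
I/O, and a command-line interface.

## The model

Agents fully occupy an `n × n` torus. Each agent has a fixed preference
*p* ∈ {1, 2} (a share *S* of agents prefers behavior 1) and a current
behavior *b* ∈ {1, 2}. An interaction between an agent showing *b* and a
partner showing *c* pays the agent

| | conforms (*b = c*) | does not conform |
|---|---|---|
| **shows preferred behavior** (*b = p*) | *A + B* | *B* |
| **shows other behavior** | *A* | 0 |

with *A* > 0 the advantage of conforming and *B* ≥ 0 the benefit of doing
what one prefers. Time advances by random sequential updating: each of
*N*/2 rounds draws a focal agent and a partner within Chebyshev range
*R*; both then imitate a same-preference neighbor whose last interaction
paid more, with probability min(1, ΔP / (*A* + *B*)) (proportional
imitation), and finally flip behavior with probability *r* (noise).

Optional costly peer punishment deducts a cost *C* from the punisher and
a fine *F = kC* (*k* > 1) from the punishee; the punishment level is
*L = (k + 1) C*. Sanctions trigger on behavior differences
(behavior-based), on violations of the punisher's private preference
(preference-based), or with an adaptive, group-pressure-dependent cost
*C(N) = C₀ (1 − N)⁴ [2 − (1 − N)²]²* where *N* is the local fraction of
non-conforming behavior. Punishers never sanction themselves into
negative cumulative payoff. Each sanction is classified **sincere** or
**hypocritical** (sanctioning what actually conforms to one's own
preference, respectively one's own displayed behavior).

A representative-agent oracle predicts the phase: an agent showing its
preference switches when *B* < (1 − 2s)(*A* + *C* + *F*), with *s* the
conforming share; for *s = S* this separates coexistence from norm
formation.

## Worked example

Two equally strong populations (S = 0.5), but population 1 starts far
more committed to its preferred behavior (p₁ = 0.9 vs p₂ = 0.4):

```r
library(normsgame)
params <- sim_params(A = 1, B = 0.5, S = 0.5, p1 = 0.9, p2 = 0.4,
                     R = 10, r = 0.01, n_rows = 40, n_cols = 40, T = 200)
run <- run_simulation(params, seed = 42)
run
#> norms_run: 200 steps on 40 x 40 torus (seed 42)
#>   final shares: b1 = 0.978, b2 = 0.022, preferred = 0.506
#>   outcome: norm1
```

Behavior 1 becomes the norm: 97.8% of agents show it, although only half
of them prefer it (`preferred = 0.506` — population 2 assimilated). With
equal commitments the same parameters instead give *coexistence*, and the
analytic oracle agrees:

```r
predicted_phase(A = 1, B = 0.5, S = 0.5)
#> [1] "coexistence"
```

Path dependence in one sweep — identical parameters, different initial
commitments, three different outcomes:

```r
phase_sweep(sim_params(A = 1, B = 0.5, R = 10, n_rows = 40, n_cols = 40, T = 200),
            axis1 = list(param = "p1", values = c(0.4, 0.9)),
            axis2 = list(param = "p2", values = c(0.4, 0.9)),
            replicates = 3, seed = 1)
#>    p1  p2 n_norm1 n_norm2 n_coexistence    majority
#> 1 0.4 0.4       0       0             3 coexistence
#> 2 0.9 0.4       2       0             1       norm1
#> 3 0.4 0.9       0       3             0       norm2
#> 4 0.9 0.9       0       0             3 coexistence
```

Ready-made scenario configurations (unpopular norms, local cultures,
punishment typology, adaptive norm emergence, norm persistence) ship with
the package: `scenario_configs()`. The CLI wraps the same functions:

```sh
Rscript inst/cli/normsgame.R run --config inst/extdata/unpopular-norm.yaml --seed 7 --out out/
Rscript inst/cli/normsgame.R phase --A 1 --out phase_analytic.csv
```

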