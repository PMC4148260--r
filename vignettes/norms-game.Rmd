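---
title: "The multi-population norms game: model, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The multi-population norms game: model, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normsgame)
```

## The scientific question

When two groups hold incompatible preferences — each would rather behave
in its own way, but everyone benefits from doing what interaction
partners do — three macroscopic outcomes are possible: one behavior
becomes a commonly shared norm, the other behavior does, or both coexist
with most agents simply doing what they prefer. `normsgame` simulates the
micro-dynamics that select among these outcomes: payoff-driven imitation
on a spatial lattice, behavioral noise, and (optionally) costly peer
sanctioning.

## Model

Agents fully occupy an `n_rows × n_cols` torus; nobody moves, and every
site interacts within Chebyshev range `R`, so all agents have
`(2R + 1)² − 1` neighbors. Each agent carries an immutable preference
`p ∈ {1, 2}` — a share `S` of agents prefers behavior 1 — and a mutable
behavior `b ∈ {1, 2}`. An interaction pays the focal agent
`A·[b = c] + B·[b = p]`, where `c` is the partner's behavior: `A > 0`
rewards conformity, `B ≥ 0` rewards acting on one's preference. The
instructive regime for sanctioning questions is `B > A`, where behaviors
coexist unless punishment changes the effective payoffs.

One time step consists of `N/2` rounds (`N` agents updated per step).
Each round:

1. **Interaction.** A focal agent is drawn uniformly with replacement; a
   partner is drawn uniformly within range `R`. Both receive the payoff
   above, stored as their *last interaction payoff*; net payoffs also
   accumulate in a lifetime *cumulative payoff*.
2. **Punishment** (if enabled, see below), which modifies both agents'
   net payoffs this round.
3. **Imitation.** Focal and partner each draw a *role model* uniformly
   among same-preference neighbors within `R` (in-group imitation,
   motivated by homophily; with no eligible neighbor the step is
   skipped). If the model's last interaction payoff is strictly higher,
   the agent adopts the model's behavior with probability
   `min(1, ΔP / (A + B))` — the proportional imitation rule. Ties never
   trigger imitation.
4. **Noise.** Focal and partner each flip to the opposite behavior with
   probability `r` ("random strategy flipping"). Preferences never
   change.

### Punishment

In the constant modes a sanction costs the punisher `C` and fines the
punishee `F = kC` with `k > 1`; the combined severity is the punishment
level `L = (k + 1)·C`. Triggers:

* **behavior-based** — the partner's behavior differs from the
  punisher's displayed behavior;
* **preference-based** — the partner's behavior differs from the
  punisher's private preference;
* **adaptive group pressure** — behavior-based trigger with cost
  `C(N) = C₀ (1 − N)⁴ [2 − (1 − N)²]²`, where `N` is the fraction of the
  punisher's range-`R` neighbors (punishee included, self excluded)
  showing a different behavior than the punisher. The cost equals `C₀`
  in a fully conforming neighborhood and vanishes when the punisher is a
  local minority, so only coincidental local majorities sanction hard.

A sanction is vetoed when paying its cost would push the punisher's
cumulative payoff below zero; the guard is evaluated against the
cumulative payoff *before* the current round's interaction payoff is
credited, and fines (unlike costs) may push the punishee arbitrarily
negative. Each sanction is classified **sincere** or **hypocritical**:
behavior-based (and adaptive) sanctions are hypocritical when the
punished behavior equals the punisher's own preference; preference-based
sanctions are hypocritical when the punished behavior equals the
punisher's own displayed behavior.

### Mean-field oracle

A representative agent showing its preference amid a conforming share
`s` earns `B + sA`; switching would earn `(1 − s)A` plus, under
behavior-based punishment, the avoided/added sanction flows, giving the
switching condition `B < (1 − 2s)(A + C + F)`. With `s = S` this yields
the predicted phase boundary `S* = (1 − B/A)/2` (at `C = F = 0`) between
coexistence and norm formation; the mirror case follows from the model's
1↔2 relabeling symmetry. `predicted_phase()` implements this and is used
as an independent oracle for the simulator at large `R`.

## Parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `A` | conformity advantage (payoff units) | 1 | payoff scale anchor |
| `B` | preference benefit (payoff units) | 0.5 | baseline regime `A > B` |
| `S` | share preferring behavior 1 | 0.5 | equal strength |
| `p1`, `p2` | initial commitments | 0.5 | uncommitted start |
| `R` | interaction range (lattice cells) | 10 | baseline "large range" |
| `r` | flip probability per update | 0.01 | small but essential noise |
| `n_rows`, `n_cols` | lattice size | 50 × 50 | resolves patterns at desk scale |
| `T` | horizon (steps) | 200 | non-adaptive scenarios settle well before |
| `k` | fine multiplier | 3 | fine exceeds cost |
| `C0` | maximum adaptive cost | 1 | strong group pressure |

## The initializer as the study-condition generator

`init_grid()` is the synthetic data generator of every experiment: it
scatters preferences uniformly at random with *exact* counts
(`round(S·N)` sites prefer 1) and, within each population, assigns the
preferred behavior to an exact fraction (`p1`, `p2`) of members by
random permutation. Exact counts rather than i.i.d. draws remove
initialization variance from phase-diagram estimates, which sharpens
replicate comparisons without changing expectations. Payoffs start at 0
— agents who have never interacted compare as payoff 0 in imitation,
the neutral element of the payoff scale.

The generator emulates a well-mixed society with fixed group
memberships; it does not emulate spatially segregated starting
conditions, correlated preferences, heterogeneous payoff parameters, or
vacancies/movement. Conclusions from passing tests therefore concern
endogenous pattern formation from mixed starts, not the fate of
pre-existing enclaves.

## Numerical and design choices

* **Neighborhood metric.** "Range" is implemented as Chebyshev distance
  (Moore neighborhood), standard for checkerboard models and the choice
  that makes neighbor counts exactly equal for all sites; a Euclidean
  option is provided (`metric = "euclidean"`) for sensitivity checks.
* **Update schedule.** Focal agents are drawn with replacement (each
  draw uniform over all `N` agents); noise applies only to the two
  agents updated in a round, matching its role as the third sub-step of
  the per-agent update rather than a global shock.
* **Stale payoffs.** Imitation compares *last interaction* payoffs,
  however old; an agent's stored payoff is not invalidated by its own
  behavior flips. This is the literal reading of payoff-based imitation
  and matters near domain walls.
* **Clipping.** Payoff differences can exceed `A + B` once fines enter;
  the adoption probability is clipped at 1, the minimal consistent
  extension of the proportional rule.
* **Punishment direction.** Both interaction partners evaluate
  sanctioning each other (focal first, then partner, with the fine
  already debited when the second guard is checked). A `mutual = FALSE`
  switch restricts sanctioning to the focal agent; halving the sanction
  flow this way weakens preference-based punishment enough that the
  20%-hypocrites regime no longer fixates, which is why mutual is the
  default.
* **Punisher-type accounting.** After a norm has fixated, the
  sincere-to-hypocritical ratio `S : (1 − S)` concerns sanctions *of the
  remaining norm-deviant behavior* (deviants are sanctioned by sincere
  majority members and by hypocritical converts). Sanctioned deviants
  also counter-sanction their conforming punishers under mutual
  punishment; those counter-sanctions are a separate flow and are
  excluded when testing the `S : (1 − S)` accounting. Event logs retain
  every sanction, so either accounting can be recomputed.
* **Outcome thresholds.** `classify_outcome()` labels `norm1`/`norm2`
  at ≥ 80% of agents showing the behavior and `coexistence` at ≥ 80%
  showing their preference, ties resolving to coexistence. The phases
  are visually obvious in snapshots; 0.8 makes them operational. Note
  that for `S` near 0.2 or 0.8 the raw behavior shares cannot separate
  a norm from coexistence — population-resolved shares (who shows what,
  given their preference) are the clean discriminator there.
* **Mean-field comparison protocol.** The representative-agent boundary
  is checked on a 64 × 64 torus at `R = 31` (near-all-to-all), starting
  fully committed (`p1 = p2 = 1`, so the conforming share around
  population 1 is exactly `S`, the premise of the derivation), horizon
  100 steps, and the boundary is located as the interpolated
  0.5-crossing of population 1's capitulation share. Smaller lattices
  shift the apparent boundary outward by up to ~0.1 in `S`: the smaller
  population escapes its metastable committed state by finite-size
  fluctuations, a real effect of the stochastic dynamics rather than a
  failure of the mean-field formula.
* **Reproducibility.** Each run consumes a single seeded RNG stream;
  sweep cells and replicates derive independent seeds deterministically
  (`derive_seed()`). The compiled and pure-R engines consume the stream
  in the identical order, so both produce bit-identical trajectories —
  the test suite uses this as a cross-implementation check.
* **Problem sizes.** Tests and the acceptance script use 24 × 24 to
  64 × 64 lattices and horizons of 100–4000 steps, chosen so that every
  scenario's qualitative regime is well inside its asymptotic behavior
  at desk scale.

## Known limitations

* At `R = 1` the behavior field coarsens like a noisy voter model, and
  domain growth is slow: by `t = 100` the mean local conformity
  (fraction of Moore neighbors sharing one's behavior) typically sits
  near 0.7 — clearly above the 0.5 of an unstructured population, but a
  stricter cutoff of 0.75 at that time is generally not met under the
  baseline noise `r = 0.01`. Pattern scale at small `R` depends on time
  and noise, and quantitative texture comparisons are out of scope.
* Phase boundaries measured from raw behavior-share thresholds shift
  with the classification threshold and with lattice size (see above);
  the shipped protocols state both.
* The model deliberately omits agent relocation, vacant sites, more
  than two behaviors, non-lattice topologies, pooled/centralized
  punishment, sanctioning of punishers, and any change of preferences
  over time.

## A minimal session

```{r example, eval = FALSE}
params <- sim_params(A = 1, B = 1.1, S = 0.5, p1 = 1, p2 = 1, R = 2,
                     r = 0.01, n_rows = 24, n_cols = 24, T = 4000)
run <- run_simulation(params, punishment_config("adaptive", k = 3, C0 = 1),
                      seed = 1, stop_share = 0.8)
classify_outcome(run$state)   # a norm, born from noise plus group pressure
run$state$t                   # how long the coexistence plateau lasted
```
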