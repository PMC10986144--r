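# cueqs

Evolutionary dynamics of **cue-based quorum sensing** in microbial threshold
public-goods games.

Many bacterial public goods — nisin and other bacteriocins are the canonical
case — double as their own quorum-sensing (QS) signal: every cell wired for
cooperation leaks a low constitutive dose of the product (a *cue*), and
full-scale production switches on only when the local signal concentration
shows that enough potential cooperators are nearby. Cheating then comes in
two flavors: **laggards** that never cooperate but harvest their neighbors'
public good, and **liars** that fake the signal without ever delivering.
`cueqs` provides a family of models for asking when cue-driven cooperation
survives both kinds of cheat, and when paying for signal detection (true
quorum sensing) is worth it.

## The model

Strategies are genotypes over three binary loci: cooperation `C` (which also
emits one free signal dose — the cue), extra signaling `S` (one additional
dose, at cost `s`), and signal response `R` (detection machinery, at cost
`r`). The 8 genotypes range from Lazy (`csr`) through Trusty (`Csr`,
unconditional cooperator), Smart (`CsR`, conditional cooperator) to Liar
(`cSr`) and Voyeur (`csR`).

Agents interact in groups of `N = 9`. Inside a group, a conditional
cooperator expresses cooperation (`γ = 1`) iff the number of signal doses
reaches the quorum threshold `Q`; the group benefit arrives iff at least `κ`
members actively cooperate. The realized metabolic cost of an agent is

```
C_i = (1 − θ_i b) (c0 + γ_i c + s_i + r_i),
```

with `θ_i = 1` iff the cooperation threshold is met in `i`'s group.
Reproduction is pairwise imitation: player `i` replaces `j` with probability

```
p_ij = 0.5 (1 + σ Δw_ij),    Δw_ij = (C_j − C_i) / ΔC_max,
ΔC_max = c + s + r + b c0,
```

and offspring may mutate at each locus (six direction-specific rates).

Four tiers share this kernel, trading realism against tractability:

| tier | function(s) | assumptions |
|---|---|---|
| mean field | `mf_flow()`, `mf_fixed_points()` | infinite population *and* groups: every group mirrors the global frequencies |
| configuration field | `cf_flow()`, `cf_fixed_points()` | infinite population, finite random groups: exact multinomial average over all `C(N+k−2, N−1)` group compositions |
| non-spatial ABM | `abm_run()` | finite population `P`, random groups, stochastic imitation |
| lattice | `lattice_run()` | `M × M` torus, Moore-neighborhood groups, adjacent-pair imitation, diffusive mixing `D` |

On the lattice, each agent's quorum is evaluated against its *own*
neighborhood, while the configuration-field tiers share one signal pool per
sampled group — the two readings of "local signal level" that the model
family is designed to compare.

## Worked example

Fixed points of the configuration-field dynamics for the three feasible
strategies (Lazy, Trusty, Smart) at benefit `b = 0.5` and cheap signal
response `r = 0.01`:

```r
library(cueqs)
p <- qs_params(b = 0.5, r = 0.01)
fp <- cf_fixed_points(p, seed_resolution = 0.05)
tidy(fp)
#> # A tibble: 5 × 7
#>    x_La  x_Tr   x_Sm class     max_re   min_re n_seeds
#>   <dbl> <dbl>  <dbl> <chr>      <dbl>    <dbl>   <int>
#> 1 0         1 0      saddle    0.183  -0.00610     121
#> 2 0.652     0 0.348  stable   -0.0557 -0.185        54
#> 3 0         0 1      unstable  0.189   0.00610      22
#> 4 0.964     0 0.0360 saddle    0.0205 -0.342        19
#> 5 1         0 0      stable   -0.0122 -0.366        13
```

Two attractors coexist: the all-Lazy state and a polymorphism of ~65% Lazy
with ~35% *Smart* — quorum-sensing cooperators persist alongside free-riders,
while unconditional Trusty is everywhere invadable. The `x_*` columns are
strategy frequencies; `max_re`/`min_re` are the extreme real parts of the
tangent-space Jacobian eigenvalues; `n_seeds` counts how many Newton seeds
converged to each point.

A spatial run from an even three-strategy start, with zero motility:

```r
set.seed(1)
traj <- lattice_run(c(La = 1, Tr = 1, Sm = 1),
                    qs_params(M = 100, b = 0.6, r = 0.01, D = 0),
                    generations = 300, record_every = 100)
traj[, 1:5]
#>   generation  x_La  x_Tr x_Bo  x_Sm
#> 1          0 0.333 0.333    0 0.333
#> 2        100 0.685 0.043    0 0.272
#> 3        200 0.645 0.003    0 0.352
#> 4        300 0.627 0.000    0 0.373
```

Trusty is eliminated but Smart clusters persist against Lazy — the viscous
lattice settles on the Lazy–Smart boundary. `autoplot(traj)` plots the
trajectory; `autoplot(attr(traj, "final_state"))` draws the final grid;
`simulated_vector_field()` and `steady_state_sweep()` build the drift-field
and parameter-sweep summaries, and `inst/scripts/qsgame` wraps all of this
for shell use.

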