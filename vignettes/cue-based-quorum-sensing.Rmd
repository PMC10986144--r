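---
title: "Modeling cue-based quorum sensing as a threshold public-goods game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cue-based quorum sensing as a threshold public-goods game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cueqs)
```

## The biological question

Quorum sensing (QS) lets a bacterium estimate how many potential cooperators
surround it before committing to an expensive collective action — bacteriocin
release, exoenzyme secretion, biofilm matrix production. In *cue-based* QS
systems the signal molecule is the public good itself, produced at a low
constitutive level by every cell whose cooperation machinery is intact:
cooperators therefore advertise honestly for free, while a non-cooperator
that wants to fake the signal must pay for a dedicated synthesis pathway.
`cueqs` implements a strategy-evolution model of this situation and asks
under which cost/benefit/threshold conditions cooperation, paid signaling
and signal response can persist against free-riders and liars.

## Strategy space and the game

Each agent carries three binary loci. `C` grants cooperation *and* one free
constitutive signal dose (the cue); `S` adds one extra dose at metabolic
cost `s`; `R` is the detection/response machinery at cost `r`. The eight
genotypes are named Lazy (`csr`), Trusty (`Csr`), Bouncer (`CSr`), Smart
(`CsR`), Nerd (`CSR`), Liar (`cSr`), Curious liar (`cSR`) and Voyeur
(`csR`). Carriers of both `C` and `R` are *conditional* cooperators: their
`C` locus is expressed only when the local dose count reaches the quorum
threshold `Q`. Carriers of `C` without `R` cooperate unconditionally.

Within an interaction group of `N = 9` agents (the focal agent included),
activation resolves in two steps: signal doses are counted (one per `C`
carrier, one per `S` carrier — a Bouncer counts twice), each conditional
cooperator compares the dose count with `Q`, and the benefit indicator
`θ` switches on when at least `κ` group members actively cooperate. The
realized metabolic cost of agent *i* is

$$C_i = (1 - \theta_i b)\,(c_0 + \gamma_i c + s_i + r_i),$$

i.e. the benefit multiplicatively discounts the *whole* metabolic burden,
signal and response costs included. We follow this literal reading
throughout; the alternative of discounting only `c_0 + c` would change cost
tables by at most `b (s + r)` and none of the qualitative regimes, but the
discounted-bracket form is the one the cost annotations of the strategy set
imply. Silent cooperation genes cost nothing; the cue is free for any `C`
carrier and is emitted whether or not the gene is currently activated
(activation has no feedback on the dose count, which keeps the group
resolution single-pass).

Reproduction is pairwise imitation. When agents *i* and *j* compete, *i*
wins with probability
$$p_{ij} = \tfrac12\,(1 + \sigma\, \Delta w_{ij}), \qquad
\Delta w_{ij} = (C_j - C_i)/\Delta C_{max},$$
where `ΔC_max = c + s + r + b c0` is the largest possible cost difference.
Because only cost differences enter, a baseline fitness constant never needs
a value. The loser's slot is overwritten by a copy of the winner, mutated
per locus with direction-specific rates (`qs_params()$mu`); probabilities
are clamped to `[0, 1]`, which matters only if a user supplies inconsistent
parameters — at `σ ≤ 1` with costs from the model itself the kernel never
leaves the unit interval.

## Parameters

`qs_params()` collects everything; defaults are the study-standard setting.

| symbol | meaning | default | notes |
|---|---|---|---|
| `c0` | baseline metabolic cost | 1 | sets the cost unit |
| `c` | cooperation cost | 0.3 | 0.2 in the benefit-rich sweeps |
| `s` | extra-signal cost | 0.01 | 1–10% of `c0` is the plausible range |
| `r` | signal-response cost | 0.01 | must be ≪ `c` for QS to ever pay |
| `b` | cooperation benefit | 0.5 | in (0, 1); multiplies as `1 − b` |
| `σ` | selection strength | 1 | weakening it only rescales time |
| `κ` | cooperation threshold | 3 | 2–6 is the evolutionarily feasible range |
| `Q` | quorum threshold | `κ` | kept equal: switching on too early/late is selected against |
| `N` | group size | 9 | a lattice Moore neighborhood |
| `P`, `M`, `G` | population, lattice side, generations | 10⁴, 100, 2000 | desk scale; the full-scale 9×10⁴ / 300 / 10⁴ setting is supported via configuration |
| `D` | mean diffusion swaps per game step | 0 | 0–1 in sweeps; 10 approximates full mixing |
| `mu` | six per-locus mutation rates | 0 | sweeps use `rho = 1e-4` on all six |

## The four model tiers

**Mean field.** With infinite population *and* infinitely large groups every
group mirrors the global frequencies, so only Lazy, Trusty and Smart can
matter (any other genotype pays a strictly higher cost than one of these at
every state). Costs become step functions of the cooperator fraction
`x_C` relative to the threshold fraction `K = κ/N`, and the dynamics is
replicator flow on negative costs — the deterministic mean of the imitation
kernel. The flow is piecewise smooth; `mf_trajectory()` integrates it with
fixed-step RK4 plus bisection onto the indicator-switching surfaces, rather
than smoothing the thresholds, so the piecewise structure of the model is
preserved exactly.

A finite-group correction matters for fixed points: an agent is a member of
its own group, so a cooperator's own dose and activity shift its effective
thresholds down by `1/N`. In the strict continuum (`offset = 0`) the Lazy/
Trusty boundary equilibrium is invisible — the flow just jumps sign at
`x_C = K`. `mf_fixed_points()` therefore defaults to `offset = 1/N`; inside
the band `[K − 1/N, K)` cooperators collect the benefit while Lazy does
not, and when `b/c > 1/(c_0 + c)` this pins a sliding (Filippov) equilibrium
at the threshold, flagged `pinned` in the output. Such points are stable
along the edge but typically saddle in the full simplex, and they dissolve
under fluctuations that jump the band — which is why they matter as
organizing structure, not as destinations.

**Configuration field.** Keeping the population infinite but groups finite,
the expected cost of a focal strategy is the exact multinomial average of
its realized cost over all compositions of its `N − 1` co-members
(`enumerate_compositions()`: 45 compositions for 3 strategies, 6435 for 8).
All members of a sampled group share one signal pool. Expected costs are
polynomials in the frequencies, so the replicator flow is smooth and
classical root-finding applies: `cf_fixed_points()` seeds a barycentric grid
(spacing 0.02), polishes each seed with damped Newton iteration on the
reduced coordinates (tolerance 1e-10 on the flow norm), merges duplicates
within 1e-6, and classifies each point by the eigenvalues of a
central-difference Jacobian taken in the simplex tangent space — transversal
directions at edge and vertex points included, which is what distinguishes
an edge-stable point from a true attractor. The multinomial weights are
evaluated as polynomials (integer powers, not `exp`/`log`), so the flow and
its Jacobian extend smoothly across the simplex boundary and vertices need
no special-casing. Mutation, when switched on, enters the flow as a linear
one-locus mixing term; simultaneous multi-locus flips are quadratic in the
rate and omitted from the deterministic flow (the stochastic engines apply
full per-locus mutation).

**Non-spatial agent-based model.** The stochastic realization of the
configuration field at finite `P`: each elementary step draws two
independent 9-agent samples without replacement (the two groups may overlap;
at `P ≫ N` this is immaterial), one random focal per group plays the
imitation game, and the loser's array slot receives the winner's (possibly
mutated) offspring. A generation is `⌊P/2⌋` steps, so each agent competes
once per generation on average.

**Lattice.** Agents occupy an `M × M` torus; a group is the 3 × 3 Moore
block around an agent. Two deliberate departures from the CF reading follow
from spatial locality. First, each conditional cooperator evaluates `Q`
against *its own* neighborhood's doses — "the signal level in its immediate
vicinity" — so a site's cost depends on the surrounding 5 × 5 block; the
CF tiers instead let the whole sampled group share the focal group's pool.
Second, competitors are adjacent (one uniform site and one of its 8 Moore
neighbors), so their groups overlap — the mechanism that makes the
well-mixed lattice *harsher* for cooperators than the CF model, since a
cooperator no longer enjoys a one-cooperator head start over its opponent's
group. Moore adjacency is used for both competition and diffusion pairing
(a von Neumann toggle exists, `pair_adjacency`); diffusion performs a
Poisson(`D`)-distributed number of adjacent-pair swaps after every game step
(a deterministic integer-plus-Bernoulli variant is available via
`diffusion_mode`; steady states are insensitive to the choice, only the
swap-count variance differs). Replacement is in place at the loser's site.
Site selection is uniform with replacement — agents participate once per
generation in expectation, not exactly once.

## Initial populations

The initializers (`abm_init()`, `lattice_init()`) realize requested
frequencies as exact counts by largest-remainder rounding and place them
uniformly at random. They emulate a well-mixed inoculum of the chosen
genotype composition — and nothing more: no spatial pre-clustering, no
empty sites, no demographic structure. Spatial correlations in lattice runs
therefore develop endogenously from the dynamics, which is exactly what the
viscosity comparisons measure; conclusions about real, pre-structured
microbial populations (colonies, biofilms with architecture) are outside
what these starts can show.

## Numerical and design choices

* **Time scales.** The deterministic tiers use replicator time with the
  `σ/ΔC_max` scaling of the imitation kernel, so one time unit is comparable
  to one generation of the stochastic tiers. Only stationary states are
  compared across tiers; trajectory shapes are compared qualitatively.
* **Problem sizes.** Tests and examples run at `M = 100`, `G ≤ 2000`,
  `P = 10⁴`, 3–5 seeds per condition — sizes chosen so the full suite
  completes on a laptop while the regime outcomes are already stable;
  sweep cells at the full published scale (`M = 300`, `G = 10⁴`,
  `P = 9 × 10⁴`) are supported through `sweep_spec(paper_scale = TRUE)` or
  the CLI `--paper-scale` flag.
* **Steady-state window.** Sweeps discard the first 50% of generations as
  burn-in and average the rest; the choice is ours (no canonical window
  exists) and `sweep_spec(burn_in = )` exposes it — at the default sizes the
  regime classifications are insensitive between 25% and 75%.
* **Seeds.** Every stochastic run consumes R's RNG only, so `set.seed()`
  makes trajectories bitwise reproducible; sweeps derive per-cell seeds from
  a master seed, making cells independent of execution order and enabling
  cached resumption.
* **Degenerate inputs.** Monomorphic states are absorbing for every tier
  without mutation; vertices are exact fixed points of both deterministic
  flows; zero-support strategies at grid points of drift fields are
  handled by exact-count rounding (a strategy absent from the rounded count
  simply stays absent).

## What the model family robustly shows

Across the tiers, four regime results recur and are pinned by the test
suite: (i) in the mean field, cooperation survives only as a
threshold-pinned Lazy/Trusty coexistence, and only when
`b/c > 1/(c_0 + c)`; (ii) finite random groups (CF) open a genuine
bistability in which a Smart/Lazy polymorphism is a second attractor when
response is cheap, with Trusty replacing Smart when response is expensive;
(iii) on the lattice, viscosity (low `D`) favors cooperators while mixing
favors free-riders, and moderate thresholds (`κ` up to ~6) let unconditional
cooperators expel Lazy entirely at zero motility, while `κ = 7` collapses
the system to Lazy; (iv) liars and signal-exaggerators stay near
mutation–selection balance except where both signal and response are nearly
free — faking a cue that honest cooperators emit for free does not pay.

## Known limitations

* The `κ = 7` collapse to Lazy is not universal at desk scale: at the most
  cooperator-friendly cost corner (`c = 0.2`, `b = 0.8`) with strictly zero
  motility, compact Trusty clusters nucleate from even starts on 100 × 100
  grids and usually take over instead — the `κ = 6` exclusion behavior
  extends one threshold higher. Any motility `D ≥ 0.2`, or the standard
  costs (`c = 0.3`, `b = 0.5`), restore the collapse. We report this as a
  genuine sensitivity of the high-threshold phase boundary to the
  cost/benefit setting at zero diffusion.
* Signal is discrete (doses), not a diffusing concentration field; there is
  no reaction–diffusion chemistry, no signal decay, and `Q = κ` is fixed
  (separate evolution of the two thresholds is out of scope).
* The lattice has no empty sites or death — population size is strictly
  constant — and generations overlap only through the random update order.
* The deterministic CF flow drops multi-locus mutation terms (O(ρ²));
  at ρ = 10⁻⁴ this is far below every other approximation error.
* Eight-strategy CF fixed-point searches are supported but expensive
  (6435 compositions per cost evaluation, 7-dimensional Newton); the
  regime analyses here restrict the deterministic tiers to the three
  feasible strategies, which the dominance argument justifies.

## A compact tour

```{r tour, eval = FALSE}
p <- qs_params(b = 0.5, r = 0.01)

# deterministic tiers
mf_fixed_points(p)
cf_fixed_points(p, seed_resolution = 0.05)
autoplot(cf_vector_field(p, resolution = 0.1))

# stochastic tiers
set.seed(1)
traj <- lattice_run(c(La = 1, Tr = 1, Sm = 1),
                    qs_params(M = 100, b = 0.6, D = 0),
                    generations = 500, record_every = 10)
autoplot(traj)
autoplot(attr(traj, "final_state"))

# steady-state genotype distributions over a (kappa, D) grid
spec <- sweep_spec(qs_params(M = 100, G = 2000, rho = 1e-4,
                             c = 0.2, b = 0.8),
                   kappa = 2:6, D = c(0, 0.5, 1))
sw <- steady_state_sweep(spec, seed = 1)
plot_sweep(sw, x_axis = "kappa")
```
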