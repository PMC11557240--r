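---
title: "Co-ageing interdependency networks: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-ageing interdependency networks: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coageing)
library(dplyr)
```

## The model

`coageing` simulates pairs of directed *interdependency networks* that damage
each other in proportion to how functional they are, and reports the
resulting cohort demography.  A network stands for one individual of a
species (a host, a competitor tree, a chess army); each node is a functional
constituent, and a directed edge `u -> v` says that `v` depends on `u`
(`u` is a *dependee* of `v`).  A node is either functional or dysfunctional,
and a functional node fails when **strictly more than half** of its
dependees are dysfunctional — fragility comes from interdependence, not from
any node-level ageing program.

### Network growth

Networks are grown one node at a time from a two-node mutually dependent
seed.  Every new node connects *inwards* to one uniformly chosen existing
node (its dependee) and *outwards* to another (which becomes its dependent),
so no disconnected sub-network can form during growth.  Two choices here
were genuinely open and are fixed as follows:

* **Seed**: two mutually dependent nodes — the smallest structure on which
  the growth rule is well defined.
* **Coincident targets**: the inward and outward draws are independent and
  may hit the same existing node, creating a 2-cycle.  Self-edges are
  impossible by construction, and since a new node carries exactly one edge
  in each direction, parallel edges cannot arise.

All members of a species share one grown topology (`topology_mode =
"shared"`), or each pair can regrow its own (`"randomized"`) with the same
node count.  For the ~100-node networks used throughout, the two modes give
statistically indistinguishable demography; calibration uses `"randomized"`
so that different master seeds differ only in sampling noise rather than in
a particular shared network realization.

### The two-round ageing step

Each species is parameterized by `species_params(n_nodes, d, r, C, f0,
phi_T)`:

| parameter | meaning | unit / range | default |
|---|---|---|---|
| `n_nodes` | network size N | count | — |
| `d` | intrinsic marking probability per node per step | \[0, 1\] | 0 |
| `r` | repair probability per damaged node per round | \[0, 1\] | 0 |
| `C` | co-ageing constant | ≥ 0 | 0 |
| `f0` | initial functional fraction (1 − prenatal damage) | (0, 1\] | 1 |
| `phi_T` | death threshold on the functional fraction | (0, 1) | 0.10 |

One time step updates species A and then species B.  A's update runs two
rounds, each of the form *mark → propagate → repair*:

1. **Intrinsic round**: every functional node is marked dysfunctional with
   probability `d_A`; the damage is propagated (below); every dysfunctional
   node is repaired with probability `r_A`.
2. **Co-ageing round**: every functional node is marked with probability
   `alpha_BA = C_A * f_B / N_B`, proportional to the opponent's functional
   fraction; propagate; repair.

B then updates identically, using A's functional fraction *as it stands at
the end of A's update this step* (the update is sequential, in that fixed
order).  A network whose functional fraction drops strictly below `phi_T`
is dead: it is frozen (no further updates) and contributes zero co-ageing
damage from the moment of death — including the remainder of the step in
which it dies.  Freezing matters: under the winner-continues convention a
surviving chess army with `d = 0` must stop dying once its opponent is
gone, and a dead antagonist must stop inflicting damage for the hazard
bump to decay.

**Propagation** applies the majority rule to the *current* state (however
old the dependee damage is), in synchronous sweeps until a fixed point is
reached: no functional node has more than half of its dependees down.  The
fixed point is idempotent and independent of node order.  Exactly "half"
(e.g. one of two dependees) is *not* enough to fail a node.

**Cause tags.**  Every dysfunctional node carries a cause: `intrinsic` if it
was directly marked in round one, `coageing` if in round two.  A node that
fails by propagation inherits the majority cause among its dysfunctional
dependees; an exact half-and-half split is tagged `intrinsic`.  (Since a
directly marked node is already dysfunctional before propagation starts and
repair clears tags, the half-split case can only involve nodes that were
never directly marked this step — the conservative intrinsic default covers
it.)  Repair clears the tag; repaired nodes are immediately re-markable,
and repair never "un-propagates" dependents.

At death the network-level cause is `intrinsic` if dysfunctional-intrinsic
nodes outnumber dysfunctional-co-ageing ones (`ns > nc`), `coageing` if
`nc > ns`, and `intrinsic` on an exact tie (a documented deterministic
tie-break; the model only specifies the strict inequalities).

**Numerical guards.**  `alpha = C * f_opp / N_opp` is clipped to 1 with a
warning if a parameterization ever pushes it above 1 (none of the shipped
conditions do).  `max_steps` defaults to ten times a pilot estimate of the
mean solo lifespan; survivors at the cap are *censored*, reported
distinctly, and never counted as deaths.

### Randomness and reproducibility

All engine randomness flows from one integer master seed through
counter-keyed `splitmix64` substreams, one per (pair, species, purpose):
topology regrowth, prenatal damage, and the marking/repair draws each have
their own stream.  Consequences worth relying on:

* cohorts are reproducible and independent of iteration order;
* a species' draw sequence depends only on its own state history, so with
  `C_A = 0` a pair member is *bitwise identical* to a solo run with the same
  seed — the co-ageing model nests the solo-ageing model exactly.

## Demography

Time is discrete (simulation steps, chess turns); there is no
continuous-time hazard estimation.  With `S(t)` the number of individuals
alive at the start of step `t` (censored-alive individuals stay in `S`
forever), the all-cause hazard is `mu(t) = [S(t) - S(t+1)] / S(t)` and the
cause-specific hazards are `mu_i(t) = d_i(t) / S(t)` for the two mutually
exclusive causes.  The all-cause hazard is computed *as the sum* of the
cause-specific ones, so the competing-risks additivity identity is exact in
floating point, not just algebraically.  Steps with `S(t) = 0` have an
undefined hazard and are reported `NA`, never zero-filled.  The interval
mortality `m = 1 - (S_tf / S_ti)^(1/dt)` generalizes this to multi-step
observation windows; its `dt = 1` case is evaluated in the discrete-hazard
form so the reduction is exact.

### Bump detection

The qualitative signature of co-ageing is a non-monotone hazard: a rise
while the antagonist inflicts damage, a local maximum near the antagonist's
mean lifespan `tau_B`, a dip as the antagonists perish, and a late-life
intrinsic rise.  `detect_bump()` smooths the series with a centred moving
average and lists its interior local extrema; a bump is a local max
followed by a local min.  On *estimated* curves two significance guards
separate this from binomial noise: steps with fewer than `min_S` survivors
are dropped (their hazard estimates are noise-dominated), and the
max-to-min drop must exceed `se_mult` standard errors of the smoothed
hazard, `sqrt(mu (1 - mu) / S) / sqrt(window)`.  The cohort-scale analyses
in this package use `window = 15`, `min_S = 20%` of the cohort and
`se_mult = 6`; these were fixed once against positive and negative control
conditions across ten master seeds.  Smoothing and guards affect detection
only — all quantitative outputs use the raw series.

## The reference study condition

The model's text-level anchors are the co-ageing contrast `C_A = 0.015`
versus `C_A = 0` and the death threshold `phi_T = 0.10` (0.15 for the small
chess networks).  The remaining values of the reference condition, which
`default_coageing_params()` returns, were chosen once — before any
acceptance checks were written — to realize the regime the theory
describes, and have not been revisited:

* `N_A = N_B = 100`: large enough that collapse is sharp and the death
  threshold uncritical, small enough for desk-scale cohorts.
* `d_A = 0.001`, `d_B = 0.010`: the antagonist is intrinsically much
  shorter-lived (`tau_B` ≈ 20–30 steps versus a solo focal lifespan of
  ≈ 300), so its death clears well before the focal species' intrinsic
  rise — the separation that makes the bump visible.
* `C_B = 0.005`: weak back-coupling; the antagonist's demise is driven
  mostly by its own damage rate.
* `r = 0`, `f0 = 1` for both: repair and prenatal damage are studied as
  sweep directions rather than baked into the baseline.

Under this condition the focal hazard rises to a maximum near `tau_B`,
dips, and rises again, while the `C_A = 0` control is monotone — the
package's acceptance checks verify exactly this, plus the trend directions
of every parameter (lifespan falls with `C_A` and `d_A`, rises with `r_A`
and `f0_A`; the bump dissipates as `C_B` grows).

A note on the lifespan statistic: under heavy censoring (large repair rates
make networks effectively immortal at any finite horizon) the mean of the
*uncensored* death times is not monotone in survival — only early deaths
remain visible.  Trend checks therefore use the restricted mean survival
time (`restricted_mean_lifespan()`), which counts censored individuals at
the horizon.

## Chess games as co-ageing systems

A chess game is mapped onto a network pair with the parametric
restrictions of a game: no damage except from the opponent (`d = 0`), no
prenatal damage (`f0 = 1`), no repair (`r = 0`), equal sizes, and a death
threshold of 0.15 (chess networks are small, and small self-sufficient
cliques otherwise linger past any meaningful death).  `C_white` is the
damage rate *received by* white, so a stronger player has the smaller `C`.
The age of a game is its length in full moves; ply counts convert as
`ceiling(ply / 2)`.

Real archives enter through `read_pgn_archive()` (standard tag-pair +
movetext PGN; `WhiteRD`/`BlackRD` tags are honoured and `rd_default = 50`
fills in when absent), followed by `filter_games()`: games are kept when
the Glicko expected outcome for white,
`E = 1 / (1 + 10^(-g(RD_w^2 + RD_b^2)(r_w - r_b)/400))` with
`g(x) = 1 / sqrt(1 + 3 q^2 x / pi^2)`, `q = ln(10)/400`, falls in a fixed
band (e.g. \[0.7, 0.8\]), the base time control matches (300 s by
default), draws are dropped, and forfeit-like terminations are excluded —
timeouts count as forfeit-like by default, since a clock loss says nothing
about the state of the defence network.  `games_to_demography()` then
treats the losing colour as dying at the game length and the winning
colour as censored-alive forever (the *winner-continues* convention), which
is what makes game demography comparable to biological cohorts and
produces the declining late-game mortality of strong players.

No external downloads are needed anywhere: `generate_pgn_archive()` writes
deterministic synthetic archives with controlled ratings, deviations, win
probabilities, lengths and known counts of draws, forfeits, timeouts,
missing-tag games and off-time-control games, so the entire pipeline is
testable against exact ground truth.

## Calibration

`fit()` minimizes a weighted sum of squared differences between simulated
and target hazard curves (all-cause, and cause-specific when the target
provides them) over free parameters declared with box bounds in
`fit_spec()`.  Design choices, all of which were open:

* **Weights** are survivor fractions `S(t)/max S` — from the target table
  when it has an `S` column, else from the simulation — because the
  binomial variance of an estimated hazard scales as `1/S`.
* **Tail restriction**: target steps with fewer than 2% of the cohort
  remaining are dropped.  The last stragglers' hazard estimates are noise,
  and penalizing a candidate for not reproducing the exact extinction time
  of another finite cohort biases the fit toward over-long-lived (too
  small `C`) parameterizations.
* **Unreachable points**: target times the candidate cohort does not reach
  at all contribute the maximal residual of 1 at their own weight, so
  degenerate short-lived fits are still disfavoured.
* **Common random numbers**: every evaluation reuses one master seed, so
  the loss is a deterministic function of the parameters and grid/simplex
  comparisons are not washed out by Monte-Carlo noise.
* **Optimizer**: coarse grid over the box, then golden-section (one free
  parameter) or Nelder–Mead (several) refinement — derivative-free by
  design, since the loss is a stochastic simulation output with no usable
  gradient.
* **Time alignment** between data time units and simulation steps is a
  declared scale factor in `fit_spec()` (fixed, not fitted, by default).

`paired_condition_fit()` implements the model's parametric-restriction
discipline for multi-condition data: shared parameters take one value
across conditions, and only the declared per-condition parameters (in
practice the co-ageing constants) move between conditions — the structure
used to contrast treated with untreated cohorts, or chess expected-outcome
bands.  The objective is the sum of per-condition losses.

Problem sizes: the shipped checks use cohorts of 2 000 pairs for
demography-level properties and trend sweeps, 10 000 for the single-node
closed form, and 2 000–5 000 per evaluation for self-fits; these sizes make
the Monte-Carlo error small relative to every asserted effect while keeping
a full run at desk scale.

## What the synthetic data does and does not show

The generators emulate the *model's* world: identical (or
identically-distributed) network topologies, homogeneous nodes, binomial
damage, exact cause bookkeeping, and chess archives whose ratings, lengths
and outcomes follow clean parametric distributions.  Passing tests
demonstrate that the implementation realizes the model faithfully — the
conservation and competing-risks identities, the solo-model reduction, the
closed forms, the phenomenology and its parameter trends, and parameter
recoverability from the model's own output.  They do not validate the model
against nature: real hosts and pathogens have heterogeneous nodes,
time-varying interdependence, and strategic rather than random attack —
simplifications inherited from the model itself.  Real chess archives
additionally have rating-dependent game lengths and termination mixes that
the synthetic generator does not attempt to mimic.

## Known limitations

* Hazards are discrete-time; no Kaplan–Meier/Nelson–Aalen estimators,
  parametric mortality laws, or confidence bands beyond the binomial SE
  reasoning in the bump detector.
* Rating *updates* (full Glicko) are out of scope; only the expected
  outcome enters.
* Fit uncertainty is reported as the evaluation trace, not as standard
  errors; the loss surface near the optimum is flat at the scale of the
  per-evaluation Monte-Carlo noise.
* Single-node networks (used for closed-form checks) cannot be produced by
  the growth rule, which requires at least two nodes; they are built with
  the explicit constructor.
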