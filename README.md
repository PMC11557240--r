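# coageing

Cohort simulation and demography of **co-ageing interdependency networks**:
pairs of directed dependency networks that damage each other in proportion
to their functional fractions, producing the non-monotone ("kink/bump")
hazard curves seen when the demographic trajectories of two populations
couple — a host ageing with its pathogen, trees suppressing each other
during stand thinning, or the two sides of a chess game.

## Who this is for

Researchers in ageing demography, ecology, and complex-systems reliability
who want to simulate coupled mortality, decompose it into competing-risks
cause-specific hazards, detect the co-ageing signature in hazard curves,
and calibrate the model's parameters against empirical hazard tables — plus
a chess pipeline (Glicko expected outcomes, PGN archives) for studying
co-ageing outside biology.

## The model in brief

Each individual is a directed network grown by random in/out attachment; a
functional node fails when **more than half of its dependees** (the nodes
it depends on) are dysfunctional.  Each time step runs two
mark–propagate–repair rounds per species:

- intrinsic round: each functional node is marked with probability *d*;
- co-ageing round: marked with probability **α = C·f_opp/N_opp**,
  proportional to the opponent's functional fraction, where *C* is the
  co-ageing constant.

Failures are tagged by cause (intrinsic vs co-ageing); a network is dead
when its functional fraction falls below the threshold φ_T (default 10%),
and its death inherits the majority node cause.  From a cohort of pairs the
package computes survivor counts S(t), the all-cause hazard
μ(t) = [S(t) − S(t+1)]/S(t), and the cause-specific hazards
μ_i(t) = d_i(t)/S(t), which sum to μ(t) exactly.  Chess games map onto the
same machinery with d = 0, r = 0, f(0) = 1, φ_T = 0.15, and the Glicko
expected outcome

E_ij = 1 / (1 + 10^(−g(RD_i² + RD_j²)(r_i − r_j)/400)),  g(x) = 1/√(1 + 3q²x/π²),  q = ln10/400

selecting games of comparable imbalance.

## Worked example

```r
library(coageing)
library(dplyr)

pars <- default_coageing_params()       # reference condition, C_A = 0.015
coh <- simulate_cohort(pars$A, pars$B, cohort_size = 2000,
                       max_steps = 3000, master_seed = 1)
glance(coh)
#>   n_pairs mean_lifespan_A deaths_A censored_A frac_coageing_A mean_lifespan_B ...
#> 1    2000            99.3     2000          0           0.511            20.0

dem <- demography(coh) |> filter(species == "A")
detect_bump(dem$mu, window = 15, S = dem$S, min_S = 400, se_mult = 6) |> head(2)
#>       t type    value
#> 1    17  max 0.0257
#> 2    36  min 0.00620
```

Read: coupled to its antagonist, species A lives 99.3 steps on average
(versus ≈ 280 solo) and 51% of its deaths are attributed to co-ageing.  Its
hazard curve rises to a local maximum at t = 17 — just before the
antagonist's mean lifespan τ_B ≈ 20.0 — then dips to a minimum as the
antagonists die off, before the late-life intrinsic rise: the co-ageing
bump.  With `default_coageing_params(0)` (the solo control) the same
analysis finds no bump.

The chess side of the package works the same way from a PGN archive:

```r
expected_outcome(1900, 1800, rd_i = 40, rd_j = 40)
#> [1] 0.6379754
games <- read_pgn_archive("games.pgn")          # or generate_pgn_archive()
kept  <- filter_games(games, e_low = 0.55, e_high = 0.70, time_control = 300)
games_to_demography(kept)                        # per-color hazard tables
```

Calibration fits free parameters (typically the co-ageing constants) to
empirical hazard tables by simulation with common random numbers:

```r
cfg  <- run_config(pars$A, pars$B, cohort_size = 2000, max_steps = 3000,
                   topology_mode = "randomized", master_seed = 11)
spec <- fit_spec(cfg, free = list(C_A = c(0.003, 0.05)), target = my_hazard_table)
fit(spec, master_seed = 11)
```

A thin command-line wrapper with `simulate`, `sweep`, `fit`, `chess` and
`fixtures` subcommands ships in `inst/cli/coageing-cli.R`.

## Package layout

- `R/`, `src/` — network growth, the two-round simulation engine (Rcpp),
  demography, Glicko/PGN pipeline, sweeps and fitting, plots and tidiers.
- `vignettes/coageing-model.Rmd` — the model, its assumptions, parameter
  meanings and defaults, and the package's design decisions.
- `tests/testthat/` — unit, property and cohort-scale acceptance tests;
  all fixtures are generated in code.
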