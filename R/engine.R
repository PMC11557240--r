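# Node states cross the R/C++ boundary as integer codes:
#   status 0 = functional, 1 = dysfunctional
#   cause  0 = none, 1 = intrinsic, 2 = coageing
STATUS_LEVELS <- c("functional", "dysfunctional")
CAUSE_LEVELS <- c("none", "intrinsic", "coageing")

state_to_tbl <- function(status, cause) {
  tibble(
    node = seq_along(status) - 1L,
    status = STATUS_LEVELS[status + 1L],
    cause = CAUSE_LEVELS[cause + 1L]
  )
}

tbl_to_state <- function(state) {
  list(
    status = match(state$status, STATUS_LEVELS) - 1L,
    cause = match(state$cause, CAUSE_LEVELS) - 1L
  )
}

#' Apply prenatal damage to a fresh network state
#'
#' Exactly `round((1 - f0) * n_nodes)` uniformly chosen nodes start
#' dysfunctional, tagged as intrinsic damage; all others are functional.
#'
#' @param n_nodes Network size.
#' @param f0 Initial functional fraction in (0, 1\].
#' @param rng_seed Integer seed; the damaged set is deterministic given it.
#' @return A node-state tibble with columns `node` (0-based), `status` and
#'   `cause`.
#' @export
apply_prenatal_damage <- function(n_nodes, f0, rng_seed = 1) {
  if (!is.numeric(f0) || length(f0) != 1 || f0 <= 0 || f0 > 1) {
    abort("`f0` must be a single value in (0, 1].",
          class = "coageing_param_error")
  }
  st <- .prenatal_cpp(as.integer(n_nodes), f0, as.double(rng_seed))
  state_to_tbl(st$status, st$cause)
}

#' Propagate damage through a network to its fixed point
#'
#' Iteratively marks every functional node that has strictly more than half
#' of its dependees dysfunctional, using synchronous sweeps, until no further
#' node qualifies.  A propagated failure inherits the majority cause among
#' its dysfunctional dependees; an exact half-and-half split is tagged
#' intrinsic.  The operation is idempotent.
#'
#' @param net A `dependency_network`.
#' @param state A node-state tibble (`node`, `status`, `cause`).
#' @return The updated node-state tibble at the propagation fixed point.
#' @export
propagate_damage <- function(net, state) {
  csr <- net_csr(net)
  st <- tbl_to_state(state)
  out <- .propagate_cpp(csr$ptr, csr$idx, st$status, st$cause)
  state_to_tbl(out$status, out$cause)
}

#' Label the cause of a network death
#'
#' At collapse, a network's death is attributed to intrinsic damage when the
#' dysfunctional-intrinsic count exceeds the dysfunctional-co-ageing count
#' (`ns > nc`) and to co-ageing damage when `nc > ns`.  An exact tie is
#' labelled intrinsic (a documented deterministic tie-break; the model text
#' only specifies the strict inequalities).
#'
#' @param ns,nc Counts of dysfunctional nodes by intrinsic / co-ageing cause.
#' @return Character vector, `"intrinsic"` or `"coageing"`.
#' @export
label_network_death <- function(ns, nc) {
  ifelse(nc > ns, "coageing", "intrinsic")
}

params_for_cpp <- function(p) {
  stopifnot(inherits(p, "species_params"))
  unclass(p)
}

#' One full time step of a network pair
#'
#' Executes species A's two rounds (intrinsic marking with probability `d`,
#' propagation, repair; then co-ageing marking with probability
#' `alpha = C * f_B / N_B`, propagation, repair), followed by species B's
#' update in identical fashion using A's end-of-update functional fraction.
#' A network at or below its death threshold is frozen and contributes zero
#' co-ageing damage.
#'
#' @param net_A,net_B `dependency_network`s.
#' @param state_A,state_B Node-state tibbles.
#' @param params_A,params_B `species_params`.
#' @param rng_seed Integer seed for this step's draws (independent substreams
#'   are derived for the two species).
#' @return A list with updated `state_A`/`state_B`, per-species functional
#'   and per-cause dysfunctional counts, and `dead_A`/`dead_B` flags
#'   indicating whether each network is below its death threshold after the
#'   step.
#' @export
step_pair <- function(net_A, net_B, state_A, state_B, params_A, params_B,
                      rng_seed = 1) {
  ca <- net_csr(net_A)
  cb <- net_csr(net_B)
  sa <- tbl_to_state(state_A)
  sb <- tbl_to_state(state_B)
  res <- .step_pair_cpp(
    ca$ptr, ca$idx, cb$ptr, cb$idx,
    sa$status, sa$cause, sb$status, sb$cause,
    params_for_cpp(params_A), params_for_cpp(params_B),
    derive_seed(rng_seed, 1, 1, 2), derive_seed(rng_seed, 1, 2, 2)
  )
  if (res$n_alpha_clipped > 0) {
    warn(sprintf("co-ageing rate alpha exceeded 1 and was clipped (%d round(s))",
                 res$n_alpha_clipped))
  }
  list(
    state_A = state_to_tbl(res$status_A, res$cause_A),
    state_B = state_to_tbl(res$status_B, res$cause_B),
    dead_A = res$dead_A, dead_B = res$dead_B,
    counts = tibble(
      species = c("A", "B"),
      f = c(res$f_A, res$f_B),
      ns = c(res$ns_A, res$ns_B),
      nc = c(res$nc_A, res$nc_B)
    )
  )
}

summary_from_cpp <- function(res, solo) {
  sp <- if (solo) "A" else c("A", "B")
  tibble(
    pair = res$pair,
    species = sp[res$species],
    death_time = res$death_time,
    death_cause = ifelse(is.na(res$death_cause), NA_character_,
                         CAUSE_LEVELS[res$death_cause + 1L]),
    censored = res$censored
  )
}

#' Simulate a cohort of co-ageing network pairs
#'
#' Runs `cohort_size` independent pairs of networks through the two-round
#' damage / propagation / repair dynamics until both members of each pair
#' are dead (or censored at `max_steps`).  Per-pair, per-species random
#' substreams are derived from `master_seed` by counter-based keying, so
#' results are reproducible and independent of iteration order.
#'
#' Set `params_B = NULL` to age species A solo: the co-ageing round then
#' receives zero antagonist damage and, by the substream construction, a solo
#' trajectory is bitwise identical to the same pair member run with
#' `C_A = 0`.
#'
#' @param params_A,params_B `species_params`; `params_B = NULL` for a solo
#'   cohort.
#' @param cohort_size Number of pairs (individuals when solo).
#' @param max_steps Step cap; survivors are censored there.  When `NULL`, a
#'   cap of 10 times a pilot estimate of the mean solo lifespan is used.
#' @param topology_mode `"shared"` (all pairs reuse one grown topology per
#'   species) or `"randomized"` (independent topologies per pair with the
#'   same N).
#' @param winner_continues If `TRUE` (default), the surviving network keeps
#'   ageing after its antagonist's death; if `FALSE`, the pair stops at the
#'   first death and the survivor is censored.
#' @param master_seed Integer master seed.
#' @param net_A,net_B Optional explicit topologies; grown from derived seeds
#'   when `NULL`.
#' @param record_trajectories If `TRUE`, keep the per-step `f`, `ns`, `nc`
#'   series of every pair member.
#' @return A `coageing_cohort` object with elements `summary` (tibble:
#'   `pair`, `species`, `death_time`, `death_cause`, `censored`),
#'   `trajectory` (tibble or `NULL`), and the run settings.
#' @examples
#' pars <- default_coageing_params()
#' coh <- simulate_cohort(pars$A, pars$B, cohort_size = 50, master_seed = 1)
#' glance(coh)
#' @export
simulate_cohort <- function(params_A, params_B = NULL, cohort_size = 1000,
                            max_steps = NULL,
                            topology_mode = c("shared", "randomized"),
                            winner_continues = TRUE, master_seed = 1,
                            net_A = NULL, net_B = NULL,
                            record_trajectories = FALSE) {
  topology_mode <- match.arg(topology_mode)
  stopifnot(inherits(params_A, "species_params"))
  if (cohort_size < 1) abort("`cohort_size` must be >= 1")
  solo <- is.null(params_B)

  if (is.null(net_A)) {
    net_A <- make_topology(params_A$n_nodes, derive_seed(master_seed, 0, 1, 0))
  }
  if (!solo && is.null(net_B)) {
    net_B <- make_topology(params_B$n_nodes, derive_seed(master_seed, 0, 2, 0))
  }
  if (is.null(max_steps)) {
    max_steps <- estimate_max_steps(params_A, params_B, master_seed)
  }

  ca <- net_csr(net_A)
  if (!solo) cb <- net_csr(net_B)
  res <- .simulate_cohort_cpp(
    ca$ptr, ca$idx, params_for_cpp(params_A),
    if (solo) NULL else cb$ptr, if (solo) NULL else cb$idx,
    if (solo) NULL else params_for_cpp(params_B),
    as.integer(cohort_size), as.integer(max_steps),
    isTRUE(winner_continues), as.double(master_seed),
    topology_mode == "randomized", isTRUE(record_trajectories)
  )
  if (res$n_alpha_clipped > 0) {
    warn(sprintf("co-ageing rate alpha exceeded 1 and was clipped in %d round(s)",
                 res$n_alpha_clipped))
  }
  traj <- NULL
  if (record_trajectories) {
    traj <- as_tibble(res$trajectory)
    traj$species <- (if (solo) "A" else c("A", "B"))[traj$species]
  }
  structure(
    list(
      summary = summary_from_cpp(res, solo),
      trajectory = traj,
      params_A = params_A, params_B = params_B,
      cohort_size = as.integer(cohort_size),
      max_steps = as.integer(max_steps),
      topology_mode = topology_mode,
      winner_continues = isTRUE(winner_continues),
      master_seed = master_seed,
      n_alpha_clipped = res$n_alpha_clipped
    ),
    class = "coageing_cohort"
  )
}

# single-node networks cannot be grown (growth needs >= 2 nodes); build the
# edgeless singleton directly
make_topology <- function(n_nodes, seed) {
  if (n_nodes >= 2) {
    grow_network(n_nodes, rng_seed = seed)
  } else {
    new_dependency_network(list(integer(0)))
  }
}

# pilot estimate of a generous step cap: 10x the mean solo lifespan of the
# longer-lived species (fallback 10000 when a pilot individual cannot die,
# e.g. in the d = 0 chess regime)
estimate_max_steps <- function(params_A, params_B, master_seed, pilot = 24) {
  est_one <- function(p) {
    if (p$d <= 0) return(NA_real_)
    coh <- simulate_cohort(p, NULL, cohort_size = pilot, max_steps = 100000L,
                           master_seed = derive_seed(master_seed, 0, 0, 99))
    dt <- coh$summary$death_time
    if (all(is.na(dt))) NA_real_ else mean(dt, na.rm = TRUE)
  }
  cand <- c(est_one(params_A), if (!is.null(params_B)) est_one(params_B))
  if (all(is.na(cand))) return(10000L)
  as.integer(max(100, ceiling(10 * max(cand, na.rm = TRUE))))
}

#' Simulate a single network pair
#'
#' Convenience wrapper around [simulate_cohort()] for one pair, always
#' recording the full trajectory.
#'
#' @inheritParams simulate_cohort
#' @param rng_seed Seed for this pair.
#' @return A `coageing_cohort` with one pair and its trajectory.
#' @export
simulate_pair <- function(params_A, params_B = NULL, max_steps = NULL,
                          winner_continues = TRUE, rng_seed = 1,
                          net_A = NULL, net_B = NULL) {
  simulate_cohort(params_A, params_B, cohort_size = 1, max_steps = max_steps,
                  winner_continues = winner_continues, master_seed = rng_seed,
                  net_A = net_A, net_B = net_B, record_trajectories = TRUE)
}

#' @export
print.coageing_cohort <- function(x, ...) {
  solo <- is.null(x$params_B)
  cat(sprintf("<coageing_cohort> %d %s, master_seed=%s\n", x$cohort_size,
              if (solo) "solo individuals" else "pairs",
              format(x$master_seed)))
  s <- x$summary %>%
    group_by(.data$species) %>%
    summarise(
      deaths = sum(!.data$censored),
      censored = sum(.data$censored),
      mean_lifespan = mean(.data$death_time[!.data$censored]),
      .groups = "drop"
    )
  print(as.data.frame(s), row.names = FALSE)
  invisible(x)
}

#' Mean lifespan of a cohort
#'
#' Mean of the uncensored death times, per species.
#'
#' @param x A `coageing_cohort` or a numeric vector of death times with `NA`
#'   for censored individuals.
#' @param species Which species, when `x` is a cohort.
#' @return A single number.
#' @export
mean_lifespan <- function(x, species = "A") {
  if (inherits(x, "coageing_cohort")) {
    x <- x$summary$death_time[x$summary$species == species]
  }
  if (all(is.na(x))) return(NA_real_)
  mean(x, na.rm = TRUE)
}

#' Restricted mean lifespan
#'
#' Mean survival time restricted to a horizon: censored individuals count at
#' the horizon, so the statistic is well defined and monotone in the
#' underlying survival even when part of the cohort outlives the
#' observation window.
#'
#' @param x A `coageing_cohort` or numeric death times with `NA` for
#'   censored.
#' @param species Which species, when `x` is a cohort.
#' @param horizon Restriction time; defaults to the cohort's `max_steps`.
#' @return A single number.
#' @export
restricted_mean_lifespan <- function(x, species = "A", horizon = NULL) {
  if (inherits(x, "coageing_cohort")) {
    if (is.null(horizon)) horizon <- x$max_steps
    x <- x$summary$death_time[x$summary$species == species]
  }
  if (is.null(horizon)) abort("`horizon` is required for raw death times")
  mean(pmin(ifelse(is.na(x), horizon, x), horizon))
}
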