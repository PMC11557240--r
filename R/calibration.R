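#' Sweep one model parameter across a grid
#'
#' Re-runs a configured cohort simulation for each value of one species
#' parameter, holding everything else fixed.  All runs share the same master
#' seed (common random numbers), so differences between grid values are not
#' inflated by Monte-Carlo noise, and the whole sweep is deterministic given
#' `master_seed`.
#'
#' @param config A `coageing_config` (the base condition).
#' @param parameter Parameter name with species suffix, e.g. `"C_A"`,
#'   `"d_B"`, `"r_A"`, `"f0_A"`.
#' @param values Numeric grid.
#' @param master_seed Master seed; defaults to the config's.
#' @return A tibble with one row per value: `parameter`, `value`,
#'   `mean_lifespan_A`, `mean_lifespan_B`, `bump_A` (bump detected in A's
#'   smoothed all-cause hazard) and a `demography` list-column.
#' @examples
#' \donttest{
#' pars <- default_coageing_params()
#' cfg <- run_config(pars$A, pars$B, cohort_size = 200)
#' sweep_parameter(cfg, "C_A", c(0, 0.015))
#' }
#' @export
sweep_parameter <- function(config, parameter, values,
                            master_seed = config$master_seed) {
  stopifnot(inherits(config, "coageing_config"))
  rows <- purrr::map(values, function(v) {
    cfg <- set_config_param(config, parameter, v)
    cfg$master_seed <- master_seed
    coh <- run_simulation(cfg)
    dem <- demography(coh)
    demA <- filter(dem, .data$species == "A")
    bump <- detect_bump(demA$mu, window = 15, S = demA$S,
                        min_S = 0.2 * demA$S[1], se_mult = 6)
    tibble(
      parameter = parameter, value = v,
      mean_lifespan_A = mean_lifespan(coh, "A"),
      mean_lifespan_B = if (is.null(cfg$params_B)) NA_real_
                        else mean_lifespan(coh, "B"),
      rmst_A = restricted_mean_lifespan(coh, "A"),
      rmst_B = if (is.null(cfg$params_B)) NA_real_
               else restricted_mean_lifespan(coh, "B"),
      bump_A = has_bump(bump),
      bump_amplitude_A = bump_amplitude(bump),
      demography = list(dem)
    )
  })
  bind_rows(rows)
}

#' Specify a simulation-based fit
#'
#' Declares which parameters are free (with box bounds), which are frozen at
#' the values in `config`, and which empirical hazard table the simulation
#' should reproduce.  The loss is a weighted sum of squared differences
#' between simulated and target hazards over every curve present in the
#' target (`mu`, and `mu_s`/`mu_c` when supplied), weighted by survivor
#' fraction `S(t) / max(S)` — taken from the target table when it carries an
#' `S` column, otherwise from the simulation — because the binomial variance
#' of an estimated hazard scales as `1/S`.
#'
#' @param config A `coageing_config` holding the frozen parameters and the
#'   per-evaluation cohort size.
#' @param free Named list of `c(lower, upper)` bounds, names as in
#'   [set_config_param()] (e.g. `list(C_A = c(0, 0.05))`).
#' @param target Tibble with a `t` column plus `mu` and/or `mu_s`, `mu_c`.
#' @param species Which simulated species the target describes.
#' @param time_scale Simulation steps per target time unit (fixed alignment
#'   scale).
#' @return A `coageing_fit_spec`.
#' @export
fit_spec <- function(config, free, target, species = "A", time_scale = 1) {
  stopifnot(inherits(config, "coageing_config"))
  if (length(free) == 0) abort("at least one free parameter is required")
  if (is.null(names(free)) || any(names(free) == "")) {
    abort("`free` must be a named list of c(lower, upper) bounds")
  }
  for (nm in names(free)) {
    b <- free[[nm]]
    if (length(b) != 2 || b[1] >= b[2]) {
      abort(sprintf("bounds for %s must be c(lower, upper)", nm))
    }
    set_config_param(config, nm, mean(b))  # validates name and bounds
  }
  curves <- intersect(c("mu", "mu_s", "mu_c"), names(target))
  if (!("t" %in% names(target)) || length(curves) == 0 || nrow(target) == 0) {
    abort("`target` must be non-empty with columns t and mu (or mu_s/mu_c)")
  }
  structure(
    list(config = config, free = free, target = target, species = species,
         curves = curves, time_scale = time_scale),
    class = "coageing_fit_spec"
  )
}

# Weighted SSE between a simulated demography and the target.  Target times
# are mapped onto simulation steps via time_scale.  Weights are the target's
# survivor fractions when the target table carries an S column (the binomial
# variance of an observed hazard scales as 1/S, so survivor-rich steps are
# the reliable ones); otherwise the simulation's survivor fractions stand
# in.  Target points the simulation cannot reach (its cohort already
# extinct) receive the maximal residual of 1 at their own weight, so
# parameter values that end the simulated cohort too early are disfavoured
# rather than silently dropped.
target_loss <- function(dem, target, curves, time_scale, s_floor = 0.02) {
  if ("S" %in% names(target)) {
    # drop the extreme tail: hazard estimates from the last few survivors
    # are dominated by noise and their absence from a candidate simulation
    # says nothing about the parameters
    target <- target[target$S >= s_floor * max(target$S), , drop = FALSE]
  }
  t_sim <- round(target$t * time_scale)
  hit <- match(t_sim, dem$t)
  ok <- !is.na(hit) & !is.na(dem$mu[hit])
  if (!any(ok)) {
    abort("target and simulation time ranges are disjoint after alignment")
  }
  if ("S" %in% names(target)) {
    w_all <- target$S / max(target$S)
  } else {
    w_all <- rep(NA_real_, nrow(target))
    w_all[ok] <- dem$S[hit[ok]] / max(dem$S)
    w_all[!ok] <- mean(w_all[ok])
  }
  loss <- 0
  for (cv in curves) {
    sim <- dem[[cv]][hit[ok]]
    obs <- target[[cv]][ok]
    loss <- loss + sum(w_all[ok] * (sim - obs)^2)
    loss <- loss + sum(w_all[!ok])  # unreachable target points, residual 1
  }
  loss
}

make_loss <- function(config, free_names, target, species, curves,
                      time_scale, master_seed) {
  force(list(config, free_names, target, species, curves, time_scale,
             master_seed))
  function(theta) {
    cfg <- config
    for (i in seq_along(free_names)) {
      cfg <- set_config_param(cfg, free_names[i], theta[i])
    }
    cfg$master_seed <- master_seed  # common random numbers
    coh <- run_simulation(cfg)
    dem <- filter(demography(coh), .data$species == !!species)
    target_loss(dem, target, curves, time_scale)
  }
}

eval_logged <- function(loss_fn, free_names, trace_env) {
  function(theta) {
    val <- loss_fn(theta)
    row <- as.list(theta)
    names(row) <- free_names
    row$loss <- val
    trace_env$rows[[length(trace_env$rows) + 1]] <- as_tibble(row)
    val
  }
}

clamped <- function(fn, lower, upper) {
  function(theta) {
    if (any(theta < lower) || any(theta > upper)) {
      return(1e6 + sum(pmax(0, theta - upper) + pmax(0, lower - theta)))
    }
    fn(theta)
  }
}

#' Fit free parameters to an empirical hazard curve
#'
#' Derivative-free, simulation-based minimization of the weighted hazard
#' loss declared in a [fit_spec()]: a coarse grid scan over the free-box,
#' followed by local refinement (golden-section for one free parameter,
#' Nelder–Mead otherwise).  Every evaluation re-simulates the cohort with
#' the same master seed (common random numbers), so the loss surface is
#' deterministic and the whole fit reproducible given `master_seed`.
#'
#' @param spec A `coageing_fit_spec`.
#' @param master_seed Seed shared by all loss evaluations.
#' @param grid_n Grid points per free dimension in the scan (total capped at
#'   about 40 evaluations for multi-parameter fits).
#' @param refine Run the local refinement stage.
#' @return A `coageing_fit`: best parameters (`par`), final `loss`, and the
#'   full evaluation log (`trace`).
#' @export
fit <- function(spec, master_seed = 1, grid_n = 7, refine = TRUE) {
  stopifnot(inherits(spec, "coageing_fit_spec"))
  free_names <- names(spec$free)
  k <- length(free_names)
  lower <- vapply(spec$free, `[`, numeric(1), 1)
  upper <- vapply(spec$free, `[`, numeric(1), 2)

  trace_env <- new.env()
  trace_env$rows <- list()
  base_loss <- make_loss(spec$config, free_names, spec$target, spec$species,
                         spec$curves, spec$time_scale, master_seed)
  loss <- eval_logged(base_loss, free_names, trace_env)

  n_per_dim <- if (k == 1) grid_n else max(3, floor(40^(1 / k)))
  grids <- lapply(seq_len(k), function(i) {
    seq(lower[i], upper[i], length.out = n_per_dim)
  })
  grid <- as.matrix(expand.grid(grids))
  grid_losses <- apply(grid, 1, loss)
  best_i <- which.min(grid_losses)
  best <- grid[best_i, ]
  best_loss <- grid_losses[best_i]

  if (refine) {
    if (k == 1) {
      lo <- grid[max(1, best_i - 1), 1]
      hi <- grid[min(nrow(grid), best_i + 1), 1]
      if (hi > lo) {
        opt <- optimize(function(x) loss(x), lower = lo, upper = hi,
                        tol = max((hi - lo) * 1e-3, 1e-8))
        if (opt$objective < best_loss) {
          best <- opt$minimum
          best_loss <- opt$objective
        }
      }
    } else {
      opt <- optim(best, clamped(loss, lower, upper), method = "Nelder-Mead",
                   control = list(maxit = 60, reltol = 1e-3))
      if (opt$value < best_loss) {
        best <- opt$par
        best_loss <- opt$value
      }
    }
  }
  par <- as.numeric(best)
  names(par) <- free_names
  structure(
    list(par = par, loss = best_loss, trace = bind_rows(trace_env$rows),
         spec = spec, master_seed = master_seed),
    class = "coageing_fit"
  )
}

#' @export
print.coageing_fit <- function(x, ...) {
  cat("<coageing_fit>\n")
  for (nm in names(x$par)) cat(sprintf("  %s = %g\n", nm, x$par[[nm]]))
  cat(sprintf("  loss = %g (%d evaluations)\n", x$loss, nrow(x$trace)))
  invisible(x)
}

#' Joint fit across experimental conditions
#'
#' Fits several hazard targets simultaneously under the model's parametric
#' restriction: `shared` parameters take a single value across all
#' conditions, while `per_condition` parameters are free to differ (e.g.
#' only the co-ageing constants move between an infected and an
#' antibiotic-treated cohort, or between two expected-outcome bands of chess
#' games).  The objective is the sum of the per-condition losses, evaluated
#' with common random numbers.
#'
#' @param config Base `coageing_config` (frozen parameters and cohort size).
#' @param targets Named list (>= 2) of target hazard tibbles.
#' @param shared Named list of `c(lower, upper)` bounds for parameters shared
#'   by all conditions; may be empty (`list()`).
#' @param per_condition Named list of bounds for parameters refit per
#'   condition.
#' @param species,time_scale As in [fit_spec()].
#' @param master_seed,grid_n,refine As in [fit()].
#' @return A `coageing_paired_fit` with tidy per-condition estimates.
#' @export
paired_condition_fit <- function(config, targets, shared = list(),
                                 per_condition, species = "A",
                                 time_scale = 1, master_seed = 1,
                                 grid_n = 5, refine = TRUE) {
  if (length(targets) < 2) abort("need at least 2 conditions")
  if (length(per_condition) == 0 && length(shared) == 0) {
    abort("at least one free parameter is required")
  }
  cond <- names(targets)
  if (is.null(cond)) cond <- paste0("condition_", seq_along(targets))
  sh_names <- names(shared)
  pc_names <- names(per_condition)
  if (length(intersect(sh_names, pc_names))) {
    abort("shared and per-condition parameter sets must be disjoint")
  }

  cond_losses <- lapply(targets, function(tg) {
    curves <- intersect(c("mu", "mu_s", "mu_c"), names(tg))
    make_loss(config, c(sh_names, pc_names), tg, species, curves,
              time_scale, master_seed)
  })
  k_sh <- length(sh_names)
  k_pc <- length(pc_names)
  k <- k_sh + k_pc * length(targets)
  lower <- c(vapply(shared, `[`, numeric(1), 1),
             rep(vapply(per_condition, `[`, numeric(1), 1), length(targets)))
  upper <- c(vapply(shared, `[`, numeric(1), 2),
             rep(vapply(per_condition, `[`, numeric(1), 2), length(targets)))

  joint <- function(theta) {
    tot <- 0
    for (j in seq_along(targets)) {
      th <- c(theta[seq_len(k_sh)],
              theta[k_sh + (j - 1) * k_pc + seq_len(k_pc)])
      tot <- tot + cond_losses[[j]](th)
    }
    tot
  }
  trace_env <- new.env(); trace_env$rows <- list()
  nm_all <- c(sh_names, as.vector(outer(pc_names, cond, paste, sep = ".")))
  logged <- eval_logged(joint, nm_all, trace_env)

  n_per_dim <- max(3, floor(60^(1 / k)))
  grids <- lapply(seq_len(k), function(i) {
    seq(lower[i], upper[i], length.out = n_per_dim)
  })
  grid <- as.matrix(expand.grid(grids))
  gl <- apply(grid, 1, logged)
  best <- grid[which.min(gl), ]
  best_loss <- min(gl)
  if (refine) {
    opt <- optim(best, clamped(logged, lower, upper), method = "Nelder-Mead",
                 control = list(maxit = 80, reltol = 1e-3))
    if (opt$value < best_loss) { best <- opt$par; best_loss <- opt$value }
  }
  est <- tibble(
    condition = rep(cond, each = k_pc),
    parameter = rep(pc_names, times = length(cond)),
    estimate = as.numeric(best[k_sh + seq_len(k_pc * length(cond))])
  )
  shared_est <- tibble(parameter = sh_names,
                       estimate = as.numeric(best[seq_len(k_sh)]))
  structure(
    list(per_condition = est, shared = shared_est, loss = best_loss,
         trace = bind_rows(trace_env$rows), master_seed = master_seed),
    class = "coageing_paired_fit"
  )
}

#' @export
print.coageing_paired_fit <- function(x, ...) {
  cat("<coageing_paired_fit>\n")
  if (nrow(x$shared)) {
    cat("shared:\n"); print(as.data.frame(x$shared), row.names = FALSE)
  }
  print(as.data.frame(x$per_condition), row.names = FALSE)
  cat(sprintf("loss = %g (%d evaluations)\n", x$loss, nrow(x$trace)))
  invisible(x)
}
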