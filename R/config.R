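#' Simulation run configuration
#'
#' Bundles the two species' parameters with the run-level settings.  All
#' parameter invariants are validated at construction time, before any
#' simulation starts.
#'
#' @param params_A,params_B `species_params` (`params_B = NULL` for a solo
#'   run).
#' @param cohort_size Number of pairs.
#' @param max_steps Step cap, or `NULL` for the pilot-based default.
#' @param topology_mode `"shared"` or `"randomized"`.
#' @param winner_continues Logical.
#' @param master_seed Integer master seed.
#' @return A `coageing_config`.
#' @export
run_config <- function(params_A, params_B = NULL, cohort_size = 2000,
                       max_steps = NULL,
                       topology_mode = c("shared", "randomized"),
                       winner_continues = TRUE, master_seed = 1) {
  topology_mode <- match.arg(topology_mode)
  stopifnot(inherits(params_A, "species_params"))
  if (!is.null(params_B)) stopifnot(inherits(params_B, "species_params"))
  if (!is.numeric(cohort_size) || cohort_size < 1) {
    abort("invalid run configuration: cohort_size (must be >= 1)")
  }
  structure(
    list(params_A = params_A, params_B = params_B,
         cohort_size = as.integer(cohort_size),
         max_steps = if (is.null(max_steps)) NULL else as.integer(max_steps),
         topology_mode = topology_mode,
         winner_continues = isTRUE(winner_continues),
         master_seed = master_seed),
    class = "coageing_config"
  )
}

#' @export
print.coageing_config <- function(x, ...) {
  cat(sprintf("<coageing_config> cohort=%d topology=%s seed=%s\n",
              x$cohort_size, x$topology_mode, format(x$master_seed)))
  cat("A: "); print(x$params_A)
  if (!is.null(x$params_B)) { cat("B: "); print(x$params_B) }
  invisible(x)
}

#' Read a run configuration from a YAML file
#'
#' The file holds flat key-value blocks `species_a:`, optionally
#' `species_b:` (each with `n_nodes`, `d`, `r`, `C`, `f0`, `phi_T`) and
#' `run:` (`cohort_size`, `max_steps`, `topology_mode`, `winner_continues`,
#' `master_seed`).  Invalid or unknown keys raise a validation error naming
#' the offending entries.
#'
#' @param path YAML file path.
#' @return A `coageing_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$species_a)) abort("config is missing the `species_a` block")
  sp <- function(block, label) {
    allowed <- c("n_nodes", "d", "r", "C", "f0", "phi_T")
    extra <- setdiff(names(block), allowed)
    if (length(extra)) {
      abort(sprintf("unknown key(s) in %s: %s", label,
                    paste(extra, collapse = ", ")))
    }
    do.call(species_params, block)
  }
  pa <- sp(cfg$species_a, "species_a")
  pb <- if (!is.null(cfg$species_b)) sp(cfg$species_b, "species_b")
  run <- cfg$run %||% list()
  allowed <- c("cohort_size", "max_steps", "topology_mode",
               "winner_continues", "master_seed")
  extra <- setdiff(names(run), allowed)
  if (length(extra)) {
    abort(sprintf("unknown key(s) in run block: %s",
                  paste(extra, collapse = ", ")))
  }
  run_config(
    pa, pb,
    cohort_size = run$cohort_size %||% 2000,
    max_steps = run$max_steps,
    topology_mode = run$topology_mode %||% "shared",
    winner_continues = run$winner_continues %||% TRUE,
    master_seed = run$master_seed %||% 1
  )
}

#' Write a run configuration to YAML
#'
#' @param config A `coageing_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  out <- list(
    species_a = unclass(config$params_A),
    run = list(cohort_size = config$cohort_size,
               topology_mode = config$topology_mode,
               winner_continues = config$winner_continues,
               master_seed = config$master_seed)
  )
  if (!is.null(config$params_B)) out$species_b <- unclass(config$params_B)
  if (!is.null(config$max_steps)) out$run$max_steps <- config$max_steps
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run a configured cohort simulation, optionally writing output tables
#'
#' Executes [simulate_cohort()] under a `coageing_config` and, when
#' `out_dir` is given, writes the per-pair summary, optional trajectories,
#' per-species hazard tables, and a YAML run log (seed, package version,
#' parameter echo) as plain delimited text.  Outputs are byte-identical
#' across runs with identical seeds.
#'
#' @param config A `coageing_config`.
#' @param record_trajectories Keep per-step node counts.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return The `coageing_cohort`, invisibly when writing.
#' @export
run_simulation <- function(config, record_trajectories = FALSE,
                           out_dir = NULL) {
  stopifnot(inherits(config, "coageing_config"))
  coh <- simulate_cohort(
    config$params_A, config$params_B,
    cohort_size = config$cohort_size, max_steps = config$max_steps,
    topology_mode = config$topology_mode,
    winner_continues = config$winner_continues,
    master_seed = config$master_seed,
    record_trajectories = record_trajectories
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
    wt(coh$summary, "summary.tsv")
    if (!is.null(coh$trajectory)) wt(coh$trajectory, "trajectory.tsv")
    dem <- demography(coh)
    for (s in unique(dem$species)) {
      wt(filter(dem, .data$species == s),
         sprintf("hazard_%s.tsv", s))
    }
    log <- list(package_version = as.character(utils::packageVersion("coageing")),
                master_seed = config$master_seed,
                cohort_size = config$cohort_size,
                max_steps = coh$max_steps,
                topology_mode = config$topology_mode,
                winner_continues = config$winner_continues,
                species_a = unclass(config$params_A))
    if (!is.null(config$params_B)) log$species_b <- unclass(config$params_B)
    yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
    return(invisible(coh))
  }
  coh
}

# "C_A", "d_B", "f0_A", "n_nodes_B", "phi_T_A" -> updated config
set_config_param <- function(config, name, value) {
  m <- regmatches(name, regexec("^(.*)_([AB])$", name))[[1]]
  if (length(m) != 3 ||
      !m[2] %in% c("n_nodes", "d", "r", "C", "f0", "phi_T")) {
    abort(sprintf("unknown parameter name: %s (expected e.g. C_A, d_B)", name))
  }
  field <- m[2]; side <- m[3]
  slot <- paste0("params_", side)
  if (is.null(config[[slot]])) {
    abort(sprintf("cannot set %s: species %s is not configured", name, side))
  }
  p <- unclass(config[[slot]])
  p[[field]] <- if (field == "n_nodes") as.integer(value) else value
  config[[slot]] <- do.call(species_params, p)
  config
}
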