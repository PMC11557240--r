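#' Hand-checkable toy networks
#'
#' Small fixed topologies used to verify the propagation rule by hand:
#'
#' * `"chain"` — nodes `0 -> 1 -> ... -> n-1`, each node depending on its
#'   predecessor; killing node 0 cascades down the chain one sweep at a time.
#' * `"two_dependee"` — three nodes where node 2 depends on both 0 and 1;
#'   node 2 fails only when *both* dependees are dysfunctional (one of two
#'   is not more than half).
#' * `"singleton"` — one node, no edges (no propagation is possible).
#'
#' @param kind Which topology.
#' @param n Chain length (chain only).
#' @return A `dependency_network`.
#' @export
toy_network <- function(kind = c("chain", "two_dependee", "singleton"),
                        n = 3) {
  kind <- match.arg(kind)
  switch(kind,
    chain = {
      dependees <- c(list(integer(0)),
                     lapply(seq_len(n - 1) - 1L, function(i) i))
      new_dependency_network(dependees)
    },
    two_dependee = new_dependency_network(
      list(integer(0), integer(0), c(0L, 1L))),
    singleton = new_dependency_network(list(integer(0)))
  )
}

#' Generate a synthetic calibration target
#'
#' Simulates a cohort under a known configuration and returns its species-A
#' hazard table, for parameter-recovery exercises where the ground truth is
#' known.  When `path` is given, the table is written as delimited text with
#' a YAML sidecar (`<path>.meta.yaml`) recording the true parameters.
#'
#' @param config A `coageing_config` (the truth).
#' @param path Optional output path for the table.
#' @param species Which species' demography to return.
#' @return The target tibble (`t`, `S`, `d_s`, `d_c`, `mu`, `mu_s`, `mu_c`).
#' @export
generate_hazard_target <- function(config, path = NULL, species = "A") {
  coh <- run_simulation(config)
  dem <- filter(demography(coh), .data$species == !!species)
  dem <- select(dem, -"species")
  if (!is.null(path)) {
    write_hazard_table(dem, path)
    meta <- list(species = species,
                 params_A = unclass(config$params_A),
                 cohort_size = config$cohort_size,
                 master_seed = config$master_seed)
    if (!is.null(config$params_B)) meta$params_B <- unclass(config$params_B)
    yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  }
  dem
}

#' Generate fixture files
#'
#' One entry point for all deterministic, fully synthetic fixtures: a PGN
#' archive with controlled composition, a simulator-generated hazard target
#' with recorded truth, or the toy networks as edge-list files.
#'
#' @param kind `"pgn_archive"`, `"hazard_target"` or `"toy_networks"`.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param ... Passed to the underlying generator
#'   ([generate_pgn_archive()], [generate_hazard_target()]).
#' @return Character vector of the files written, invisibly.
#' @export
make_fixtures <- function(kind = c("pgn_archive", "hazard_target",
                                   "toy_networks"),
                          dir = ".", seed = 1, ...) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- switch(kind,
    pgn_archive = {
      p <- file.path(dir, "archive.pgn")
      generate_pgn_archive(p, seed = seed, ...)
      p
    },
    hazard_target = {
      p <- file.path(dir, "hazard_target.tsv")
      args <- list(...)
      cfg <- args$config
      if (is.null(cfg)) {
        pars <- default_coageing_params()
        cfg <- run_config(pars$A, pars$B, cohort_size = 500,
                          master_seed = seed)
      }
      generate_hazard_target(cfg, path = p)
      c(p, paste0(p, ".meta.yaml"))
    },
    toy_networks = {
      kinds <- c("chain", "two_dependee")
      vapply(kinds, function(k) {
        p <- file.path(dir, paste0(k, ".edges.tsv"))
        write_edgelist(toy_network(k), p)
        p
      }, character(1))
    }
  )
  invisible(files)
}
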