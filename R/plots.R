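#' Plot hazard curves
#'
#' Line plot of the all-cause hazard, with the cause-specific components
#' overlaid when present.  Smoothing is presentational only.
#'
#' @param dem A demography tibble ([demography()], [hazard_curve()],
#'   [cause_specific_hazards()] or [games_to_demography()] output).
#' @param smooth_window Odd moving-average window (1 = raw).
#' @return A ggplot object.
#' @export
plot_hazard <- function(dem, smooth_window = 1) {
  group_col <- intersect(c("species", "color"), names(dem))
  curves <- intersect(c("mu", "mu_s", "mu_c"), names(dem))
  long <- dem %>%
    tidyr::pivot_longer(dplyr::all_of(curves), names_to = "curve",
                        values_to = "hazard") %>%
    filter(!is.na(.data$hazard))
  grp <- if (length(group_col)) group_col[1] else NULL
  if (smooth_window > 1) {
    long <- long %>%
      group_by(dplyr::across(dplyr::all_of(c(grp, "curve")))) %>%
      mutate(hazard = smooth_hazard(.data$hazard, smooth_window)) %>%
      ungroup()
  }
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$hazard,
                                          linetype = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time step", y = expression(mu(t)),
                  linetype = "curve") +
    ggplot2::theme_minimal()
  if (!is.null(grp)) {
    p <- p + ggplot2::aes(colour = .data[[grp]]) +
      ggplot2::labs(colour = grp)
  }
  p
}

#' Plot a simulated cohort
#'
#' @param object A `coageing_cohort`.
#' @param type `"hazard"` (per-species hazard curves), `"survival"`
#'   (survivor counts), or `"trajectory"` (per-pair functional fractions;
#'   requires `record_trajectories = TRUE`).
#' @param smooth_window Passed to [plot_hazard()] for `type = "hazard"`.
#' @param max_pairs Trajectories plotted at most (default 50).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coageing_cohort <- function(object,
                                     type = c("hazard", "survival",
                                              "trajectory"),
                                     smooth_window = 1, max_pairs = 50, ...) {
  type <- match.arg(type)
  if (type == "hazard") {
    return(plot_hazard(demography(object), smooth_window))
  }
  if (type == "survival") {
    dem <- demography(object)
    return(
      ggplot2::ggplot(dem, ggplot2::aes(x = .data$t, y = .data$S,
                                        colour = .data$species)) +
        ggplot2::geom_step() +
        ggplot2::labs(x = "time step", y = "survivors S(t)") +
        ggplot2::theme_minimal()
    )
  }
  if (is.null(object$trajectory)) {
    abort("no trajectories recorded; rerun with record_trajectories = TRUE")
  }
  n_a <- object$params_A$n_nodes
  n_b <- if (is.null(object$params_B)) NA_integer_ else object$params_B$n_nodes
  tr <- object$trajectory %>%
    filter(.data$pair <= max_pairs) %>%
    mutate(frac = .data$f / ifelse(.data$species == "A", n_a, n_b))
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$t, y = .data$frac,
                                   group = interaction(.data$pair,
                                                       .data$species),
                                   colour = .data$species)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "time step", y = "functional fraction f(t)/N") +
    ggplot2::theme_minimal()
}

#' Plot a fit against its target
#'
#' @param object A `coageing_fit`.
#' @param ... Unused.
#' @return A ggplot object: target hazards as points, the re-simulated best
#'   fit as lines.
#' @export
autoplot.coageing_fit <- function(object, ...) {
  spec <- object$spec
  cfg <- spec$config
  for (nm in names(object$par)) {
    cfg <- set_config_param(cfg, nm, object$par[[nm]])
  }
  cfg$master_seed <- object$master_seed
  dem <- filter(demography(run_simulation(cfg)),
                .data$species == !!spec$species)
  tgt <- spec$target %>%
    tidyr::pivot_longer(dplyr::all_of(spec$curves), names_to = "curve",
                        values_to = "hazard") %>%
    mutate(t = round(.data$t * spec$time_scale))
  sim <- dem %>%
    tidyr::pivot_longer(dplyr::all_of(spec$curves), names_to = "curve",
                        values_to = "hazard") %>%
    filter(!is.na(.data$hazard))
  ggplot2::ggplot(mapping = ggplot2::aes(x = .data$t, y = .data$hazard,
                                         colour = .data$curve)) +
    ggplot2::geom_point(data = tgt, alpha = 0.6) +
    ggplot2::geom_line(data = sim) +
    ggplot2::labs(x = "time step", y = expression(mu(t))) +
    ggplot2::theme_minimal()
}
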