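#' Per-species model parameters
#'
#' Bundles the parameters governing one species' network dynamics:
#'
#' * `n_nodes` — network size N.
#' * `d` — per-step intrinsic marking probability (round one).
#' * `r` — per-round repair probability.
#' * `C` — co-ageing constant: the antagonist-driven marking probability is
#'   `alpha = C * f_opp / N_opp` (round two).
#' * `f0` — initial functional fraction; `1 - f0` is the prenatal damage.
#' * `phi_T` — death threshold: the network is dead once its functional
#'   fraction drops strictly below `phi_T` (default 0.10).
#'
#' @param n_nodes Network size, integer >= 1.
#' @param d Intrinsic damage probability in \[0, 1\].
#' @param r Repair probability in \[0, 1\].
#' @param C Co-ageing constant, >= 0.
#' @param f0 Initial functional fraction in (0, 1\].
#' @param phi_T Death threshold fraction in (0, 1), strictly below `f0`.
#' @return A `species_params` object.
#' @examples
#' species_params(n_nodes = 100, d = 0.002, C = 0.015)
#' @export
species_params <- function(n_nodes, d = 0, r = 0, C = 0, f0 = 1,
                           phi_T = 0.10) {
  bad <- character(0)
  chk <- function(ok, name) if (!isTRUE(ok)) bad <<- c(bad, name)
  chk(is.numeric(n_nodes) && length(n_nodes) == 1 && n_nodes >= 1 &&
        n_nodes == round(n_nodes), "n_nodes (integer >= 1)")
  chk(is.numeric(d) && length(d) == 1 && d >= 0 && d <= 1, "d (in [0,1])")
  chk(is.numeric(r) && length(r) == 1 && r >= 0 && r <= 1, "r (in [0,1])")
  chk(is.numeric(C) && length(C) == 1 && C >= 0, "C (>= 0)")
  chk(is.numeric(f0) && length(f0) == 1 && f0 > 0 && f0 <= 1, "f0 (in (0,1])")
  chk(is.numeric(phi_T) && length(phi_T) == 1 && phi_T > 0 && phi_T < 1,
      "phi_T (in (0,1))")
  if (length(bad) == 0 && phi_T >= f0) bad <- c(bad, "phi_T (must be < f0)")
  if (length(bad)) {
    abort(paste0("invalid species parameters: ", paste(bad, collapse = ", ")),
          class = "coageing_param_error")
  }
  structure(
    list(n_nodes = as.integer(n_nodes), d = d, r = r, C = C, f0 = f0,
         phi_T = phi_T),
    class = "species_params"
  )
}

#' @export
print.species_params <- function(x, ...) {
  cat(sprintf(
    "<species_params> N=%d d=%g r=%g C=%g f0=%g phi_T=%g\n",
    x$n_nodes, x$d, x$r, x$C, x$f0, x$phi_T))
  invisible(x)
}

#' Species parameters for the chess regime
#'
#' Chess armies receive no damage other than that inflicted by the opponent
#' (`d = 0`), start undamaged (`f0 = 1`), cannot repair (`r = 0`), and the
#' two sides have exactly equal size.  The death threshold defaults to 0.15,
#' the value used for small chess-like networks.
#'
#' @param n_nodes Network size shared by both colors.
#' @param C_white,C_black Co-ageing constants: `C_white` is the damage rate
#'   *received by* white, so a stronger white has a smaller `C_white`.
#' @param phi_T Death threshold (default 0.15).
#' @return A list with `white` and `black` `species_params`.
#' @export
chess_regime_params <- function(n_nodes, C_white, C_black, phi_T = 0.15) {
  list(
    white = species_params(n_nodes, d = 0, r = 0, C = C_white, f0 = 1,
                           phi_T = phi_T),
    black = species_params(n_nodes, d = 0, r = 0, C = C_black, f0 = 1,
                           phi_T = phi_T)
  )
}

#' Default co-ageing study condition
#'
#' A reference parameterization in which a focal species A (co-ageing
#' constant `C_A = 0.015`) is coupled to a shorter-lived antagonist B; the
#' resulting all-cause hazard of A shows the characteristic co-ageing bump
#' near the antagonist's mean lifespan, and setting `C_A = 0` recovers a
#' monotone solo-ageing hazard.  See the package vignette for how the
#' non-prescribed values were chosen.
#'
#' @param C_A Co-ageing constant of the focal species (default 0.015).
#' @return A list with `A` and `B` `species_params`.
#' @export
default_coageing_params <- function(C_A = 0.015) {
  list(
    A = species_params(n_nodes = 100, d = 0.001, r = 0, C = C_A, f0 = 1,
                       phi_T = 0.10),
    B = species_params(n_nodes = 100, d = 0.010, r = 0, C = 0.005, f0 = 1,
                       phi_T = 0.10)
  )
}
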