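#' Glicko attenuation factor
#'
#' `g(x) = 1 / sqrt(1 + 3 q^2 x / pi^2)` with `q = ln(10) / 400`, evaluated
#' at the combined squared rating deviation `x = RD_i^2 + RD_j^2`.  The
#' factor lies in (0, 1], equals 1 at zero deviation, and strictly decreases
#' with `x`: the less accurately the ratings are known, the more the
#' expected outcome is pulled toward 1/2.
#'
#' @param rd_combined_sq Combined squared rating deviation, >= 0 (vectorized).
#' @return Attenuation factor in (0, 1].
#' @export
glicko_g <- function(rd_combined_sq) {
  if (any(rd_combined_sq < 0)) {
    abort("`rd_combined_sq` must be >= 0 (it is RD_i^2 + RD_j^2)")
  }
  q <- log(10) / 400
  1 / sqrt(1 + 3 * q^2 * rd_combined_sq / pi^2)
}

#' Glicko expected game outcome
#'
#' The expected score of player i against player j,
#' `E_ij = 1 / (1 + 10^(-g(RD_i^2 + RD_j^2) (r_i - r_j) / 400))`,
#' where `r` are Elo ratings and `RD` rating deviations.  `E_ij + E_ji = 1`
#' for any inputs, `E = 1/2` at equal ratings, and as both deviations tend
#' to zero the formula reduces to the plain Elo expectation.
#'
#' @param rating_i,rating_j Elo ratings (vectorized).
#' @param rd_i,rd_j Rating deviations in Elo points, >= 0.
#' @return Expected outcome in (0, 1).
#' @examples
#' expected_outcome(2000, 1600)            # 10/11 with exact ratings
#' expected_outcome(1900, 1800, rd_i = 80, rd_j = 120)
#' @export
expected_outcome <- function(rating_i, rating_j, rd_i = 0, rd_j = 0) {
  if (any(rd_i < 0) || any(rd_j < 0)) abort("rating deviations must be >= 0")
  g <- glicko_g(rd_i^2 + rd_j^2)
  1 / (1 + 10^(-g * (rating_i - rating_j) / 400))
}
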