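#' All-cause survival and hazard curve from death times
#'
#' Builds the discrete-time survivor counts `S(t)` and the all-cause hazard
#' `mu(t) = [S(t) - S(t+1)] / S(t)`, where `S(t)` counts the individuals
#' alive at the beginning of step `t` (censored-alive individuals remain in
#' `S` forever and never enter a death numerator).  Steps where `S(t) = 0`
#' have an undefined hazard, reported as `NA`, never zero-filled.
#'
#' @param death_times Positive integer death times; `NA` marks a
#'   censored-alive individual.
#' @param max_t Last step of the table; defaults to the latest death time.
#' @return A tibble with columns `t` (1-based step), `S`, `deaths`, `mu`.
#' @examples
#' hazard_curve(c(1, 1, 2, 3, 3, 3, NA))
#' @export
hazard_curve <- function(death_times, max_t = NULL) {
  check_death_times(death_times, max_t)
  if (is.null(max_t)) max_t <- max(death_times, na.rm = TRUE)
  max_t <- as.integer(max_t)
  n0 <- length(death_times)
  d <- tabulate(death_times[!is.na(death_times)], nbins = max_t)
  S <- n0 - c(0L, cumsum(d))[seq_len(max_t)]
  tibble(
    t = seq_len(max_t),
    S = as.integer(S),
    deaths = as.integer(d),
    mu = ifelse(S > 0, d / S, NA_real_)
  )
}

check_death_times <- function(death_times, max_t) {
  if (length(death_times) == 0) {
    abort("empty cohort: no death times supplied")
  }
  obs <- death_times[!is.na(death_times)]
  if (any(obs < 1 | obs != round(obs))) {
    abort("death times must be positive integers (NA = censored)")
  }
  if (length(obs) == 0 && is.null(max_t)) {
    abort("all individuals are censored; supply `max_t`")
  }
  invisible(TRUE)
}

#' Cause-specific hazard decomposition
#'
#' Competing-risks decomposition of a cohort's mortality: each death has
#' exactly one cause (`"intrinsic"` or `"coageing"`), the cause-specific
#' hazards are `mu_i(t) = d_i(t) / S(t)`, and the all-cause hazard is exactly
#' their sum at every step where `S(t) > 0`.
#'
#' @inheritParams hazard_curve
#' @param death_causes Character vector aligned with `death_times`
#'   (`"intrinsic"` / `"coageing"`; ignored, may be `NA`, for censored
#'   individuals).
#' @return A tibble with columns `t`, `S`, `d_s`, `d_c`, `mu`, `mu_s`,
#'   `mu_c`.
#' @export
cause_specific_hazards <- function(death_times, death_causes, max_t = NULL) {
  check_death_times(death_times, max_t)
  obs <- !is.na(death_times)
  known <- death_causes[obs]
  if (any(!known %in% c("intrinsic", "coageing"))) {
    abort("unknown death cause label; expected \"intrinsic\" or \"coageing\"")
  }
  if (is.null(max_t)) max_t <- max(death_times, na.rm = TRUE)
  max_t <- as.integer(max_t)
  n0 <- length(death_times)
  ds <- tabulate(death_times[obs & death_causes == "intrinsic"], nbins = max_t)
  dc <- tabulate(death_times[obs & death_causes == "coageing"], nbins = max_t)
  d <- ds + dc
  S <- n0 - c(0L, cumsum(d))[seq_len(max_t)]
  # the all-cause hazard is the sum of the cause-specific hazards; computing
  # it as that sum keeps the additivity identity exact in floating point
  tibble(
    t = seq_len(max_t),
    S = as.integer(S),
    d_s = as.integer(ds),
    d_c = as.integer(dc),
    mu = ifelse(S > 0, ds / S + dc / S, NA_real_),
    mu_s = ifelse(S > 0, ds / S, NA_real_),
    mu_c = ifelse(S > 0, dc / S, NA_real_)
  )
}

#' Cohort demography tables
#'
#' Per-species survival, death counts by cause, and all-cause plus
#' cause-specific hazards for a simulated cohort.
#'
#' @param cohort A `coageing_cohort`.
#' @param max_t Last tabulated step; defaults to the cohort's latest death.
#' @return A tibble with a `species` column followed by the columns of
#'   [cause_specific_hazards()].
#' @export
demography <- function(cohort, max_t = NULL) {
  stopifnot(inherits(cohort, "coageing_cohort"))
  if (is.null(max_t)) {
    if (all(is.na(cohort$summary$death_time))) {
      max_t <- cohort$max_steps
    } else {
      max_t <- max(cohort$summary$death_time, na.rm = TRUE)
    }
  }
  cohort$summary %>%
    group_by(.data$species) %>%
    dplyr::group_modify(~ cause_specific_hazards(.x$death_time,
                                                 .x$death_cause, max_t)) %>%
    ungroup()
}

#' Interval mortality rate
#'
#' Annualized (per-unit-time) mortality over an observation interval:
#' `m = 1 - (S_tf / S_ti)^(1 / delta_t)`.  With `delta_t = 1` this reduces
#' exactly to the discrete hazard `[S(t) - S(t+1)] / S(t)`.
#'
#' @param S_ti,S_tf Survivor counts at the start and end of the interval;
#'   requires `S_ti >= S_tf > 0`.
#' @param delta_t Interval length in time units, > 0.
#' @return Mortality per unit time (vectorized).
#' @examples
#' interval_mortality(100, 81, delta_t = 2)  # 0.10
#' @export
interval_mortality <- function(S_ti, S_tf, delta_t = 1) {
  if (any(delta_t <= 0)) abort("`delta_t` must be > 0")
  if (any(S_tf <= 0)) abort("`S_tf` must be > 0")
  if (any(S_tf > S_ti)) abort("survivors cannot increase: S_tf > S_ti")
  out <- 1 - (S_tf / S_ti)^(1 / delta_t)
  # the unit-interval case reduces algebraically to the discrete hazard;
  # evaluate it in that form so the identity is exact in floating point
  unit <- delta_t == 1
  if (any(unit)) {
    out[unit] <- ((S_ti - S_tf) / S_ti)[unit]
  }
  out
}

#' Smooth a hazard series with a centred moving average
#'
#' `window = 1` is the identity; endpoints use truncated windows.  Undefined
#' (`NA`) tail entries, which arise once `S(t) = 0`, are left `NA` and do not
#' contaminate the defined prefix.
#'
#' @param mu Numeric hazard series.
#' @param window Odd window width, >= 1.
#' @return The smoothed series, same length as `mu`.
#' @export
smooth_hazard <- function(mu, window = 5) {
  if (window < 1 || window %% 2 != 1) abort("`window` must be odd and >= 1")
  if (window == 1) return(mu)
  n <- length(mu)
  ok <- !is.na(mu)
  h <- (window - 1) / 2
  out <- rep(NA_real_, n)
  for (i in which(ok)) {
    lo <- max(1, i - h)
    hi <- min(n, i + h)
    v <- mu[lo:hi][ok[lo:hi]]
    out[i] <- mean(v)
  }
  out
}

#' Detect the co-ageing bump in a hazard series
#'
#' Smooths the series, then locates its interior local extrema.  A "bump" is
#' present when a local maximum is followed by a local minimum: the hazard
#' rises while the antagonist inflicts damage, dips as the antagonists
#' perish, and rises again from intrinsic damage.  Monotone or constant
#' series yield no extrema.  Plateau extrema are reported at the plateau's
#' midpoint.
#'
#' For estimated hazard curves, optional significance guards separate a
#' macroscopic bump from binomial sampling noise: `S`/`min_S` truncate the
#' series where too few survivors remain for the hazard estimate to be
#' reliable, and a max-then-min pair only counts as a bump when its
#' amplitude exceeds both `min_prominence` times the range of the smoothed
#' series and `se_mult` standard errors of the smoothed hazard at the two
#' extrema (the binomial SE of a window-averaged hazard estimate is about
#' `sqrt(mu (1 - mu) / S) / sqrt(window)`).  All guards default to off: any
#' local max followed by a local min is then a bump.
#'
#' @param mu Numeric hazard series (length >= 3); `NA` tail entries are
#'   ignored.
#' @param window Smoothing window passed to [smooth_hazard()].
#' @param S Optional survivor counts aligned with `mu`.
#' @param min_S Steps with `S < min_S` are dropped before detection.
#' @param min_prominence Minimum bump amplitude as a fraction of the
#'   smoothed series' range.
#' @param se_mult Minimum bump amplitude in units of the smoothed hazard's
#'   standard error (requires `S`).
#' @return A tibble of extrema (`t` index, `type` `"max"`/`"min"`, `value`),
#'   with attributes `has_bump` and `bump_amplitude` (the largest smoothed
#'   drop from a local max to a later local min, 0 when none).  Use
#'   [has_bump()] to read the flag.
#' @export
detect_bump <- function(mu, window = 5, S = NULL, min_S = 0,
                        min_prominence = 0, se_mult = 0) {
  if (length(mu) < 3) abort("series must have length >= 3")
  if (!is.null(S) && min_S > 0) {
    mu[S < min_S] <- NA_real_
  }
  s <- smooth_hazard(mu, window)
  ext <- find_extrema(s)
  floor_abs <- 0
  if (min_prominence > 0) {
    floor_abs <- min_prominence * diff(range(s, na.rm = TRUE))
  }
  se <- rep(0, nrow(ext))
  if (se_mult > 0) {
    if (is.null(S)) abort("`se_mult` requires survivor counts `S`")
    v <- pmin(pmax(ext$value, 0), 1)
    se <- sqrt(v * (1 - v) / S[ext$t]) / sqrt(window)
  }
  bump <- FALSE
  best_amp <- 0
  is_max <- ext$type == "max"
  for (i in which(is_max)) {
    for (j in which(!is_max)) {
      if (ext$t[j] <= ext$t[i]) next
      amp <- ext$value[i] - ext$value[j]
      if (amp > best_amp) best_amp <- amp
      if (amp >= max(floor_abs, se_mult * max(se[i], se[j]))) bump <- TRUE
    }
  }
  attr(ext, "has_bump") <- bump
  attr(ext, "bump_amplitude") <- best_amp
  ext
}

#' @rdname detect_bump
#' @export
bump_amplitude <- function(mu, ...) {
  if (is.numeric(mu)) mu <- detect_bump(mu, ...)
  attr(mu, "bump_amplitude") %||% 0
}

find_extrema <- function(x) {
  keep <- which(!is.na(x))
  empty <- tibble(t = integer(0), type = character(0), value = numeric(0))
  if (length(keep) < 3) return(empty)
  x <- x[seq_len(max(keep))]
  dx <- diff(x)
  sgn <- sign(dx)
  nz <- which(sgn != 0)
  if (length(nz) < 2) return(empty)
  rows <- list()
  for (k in 2:length(nz)) {
    a <- sgn[nz[k - 1]]
    b <- sgn[nz[k]]
    if (a == b) next
    idx <- floor((nz[k - 1] + 1 + nz[k]) / 2)  # plateau midpoint
    rows[[length(rows) + 1]] <- tibble(
      t = as.integer(idx),
      type = if (a > 0) "max" else "min",
      value = x[idx]
    )
  }
  if (length(rows) == 0) return(empty)
  bind_rows(rows)
}


#' @rdname detect_bump
#' @param x A hazard series or the result of [detect_bump()].
#' @param ... Passed on to [detect_bump()] when `x` is a series.
#' @export
has_bump <- function(x, ...) {
  if (is.numeric(x)) x <- detect_bump(x, ...)
  isTRUE(attr(x, "has_bump"))
}

#' Write / read a hazard table
#'
#' Plain tab-delimited text with a one-line header; the same format is read
#' back as a calibration target.
#'
#' @param x A hazard table (any tibble with a `t` column).
#' @param path File path.
#' @return The path (write) or a tibble (read).
#' @export
write_hazard_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hazard_table
#' @export
read_hazard_table <- function(path) {
  as_tibble(read.table(path, header = TRUE, sep = "\t"))
}
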