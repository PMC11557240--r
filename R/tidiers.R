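#' Tidy a simulated cohort
#'
#' @param x A `coageing_cohort`.
#' @param ... Unused.
#' @return The per-individual summary tibble: `pair`, `species`,
#'   `death_time`, `death_cause`, `censored`.
#' @export
tidy.coageing_cohort <- function(x, ...) {
  x$summary
}

#' One-row cohort summary
#'
#' @param x A `coageing_cohort`.
#' @param ... Unused.
#' @return A tibble with cohort size, per-species mean lifespans, death and
#'   censoring counts, and the fraction of deaths attributed to co-ageing.
#' @export
glance.coageing_cohort <- function(x, ...) {
  one <- function(sp) {
    s <- filter(x$summary, .data$species == sp)
    if (nrow(s) == 0) {
      return(tibble(mean_lifespan = NA_real_, deaths = NA_integer_,
                    censored = NA_integer_, frac_coageing = NA_real_))
    }
    dead <- filter(s, !.data$censored)
    tibble(
      mean_lifespan = if (nrow(dead)) mean(dead$death_time) else NA_real_,
      deaths = nrow(dead),
      censored = sum(s$censored),
      frac_coageing = if (nrow(dead)) {
        mean(dead$death_cause == "coageing")
      } else NA_real_
    )
  }
  a <- one("A")
  b <- one("B")
  tibble(
    n_pairs = x$cohort_size,
    mean_lifespan_A = a$mean_lifespan, deaths_A = a$deaths,
    censored_A = a$censored, frac_coageing_A = a$frac_coageing,
    mean_lifespan_B = b$mean_lifespan, deaths_B = b$deaths,
    censored_B = b$censored, frac_coageing_B = b$frac_coageing
  )
}

#' Tidy a fitted parameter set
#'
#' @param x A `coageing_fit`.
#' @param ... Unused.
#' @return A tibble with `parameter`, `estimate`, `lower`, `upper` (the
#'   search bounds).
#' @export
tidy.coageing_fit <- function(x, ...) {
  tibble(
    parameter = names(x$par),
    estimate = as.numeric(x$par),
    lower = vapply(x$spec$free, `[`, numeric(1), 1),
    upper = vapply(x$spec$free, `[`, numeric(1), 2)
  )
}

#' One-row fit summary
#'
#' @param x A `coageing_fit`.
#' @param ... Unused.
#' @return A tibble with the final loss, evaluation count, cohort size per
#'   evaluation, and master seed.
#' @export
glance.coageing_fit <- function(x, ...) {
  tibble(
    loss = x$loss,
    n_eval = nrow(x$trace),
    cohort_size = x$spec$config$cohort_size,
    master_seed = x$master_seed
  )
}

#' Tidy a joint multi-condition fit
#'
#' @param x A `coageing_paired_fit`.
#' @param ... Unused.
#' @return Per-condition parameter estimates (shared parameters carry
#'   `condition = NA`).
#' @export
tidy.coageing_paired_fit <- function(x, ...) {
  bind_rows(
    if (nrow(x$shared)) mutate(x$shared, condition = NA_character_,
                               .before = 1),
    x$per_condition
  )
}
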