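test_that("prenatal damage hits exactly the rounded node count", {
  st <- apply_prenatal_damage(100, f0 = 1, rng_seed = 1)
  expect_true(all(st$status == "functional"))
  expect_true(all(st$cause == "none"))

  st <- apply_prenatal_damage(100, f0 = 0.9, rng_seed = 1)
  expect_equal(sum(st$status == "dysfunctional"), 10)
  expect_true(all(st$cause[st$status == "dysfunctional"] == "intrinsic"))

  st2 <- apply_prenatal_damage(100, f0 = 0.9, rng_seed = 1)
  expect_identical(st, st2)
  st3 <- apply_prenatal_damage(100, f0 = 0.9, rng_seed = 2)
  expect_false(identical(st, st3))

  expect_error(apply_prenatal_damage(100, f0 = 0),
               class = "coageing_param_error")
  expect_error(apply_prenatal_damage(100, f0 = 1.2),
               class = "coageing_param_error")
})

test_that("a node fails only when strictly more than half its dependees are down", {
  motif <- toy_network("two_dependee")
  # one of two dependees down: 1/2 is not more than half
  out <- propagate_damage(motif, make_state(3, dead = 0L))
  expect_equal(state_of(out, 2), "functional")
  # both dependees down: 2/2 > 1/2
  out <- propagate_damage(motif, make_state(3, dead = c(0L, 1L)))
  expect_equal(state_of(out, 2), "dysfunctional")
})

test_that("damage cascades down a chain to an idempotent fixed point", {
  chain <- toy_network("chain", n = 3)
  out <- propagate_damage(chain, make_state(3, dead = 0L))
  expect_true(all(out$status == "dysfunctional"))
  # propagated failures inherit the dependee's cause
  expect_equal(cause_of(out, c(1, 2)), c("intrinsic", "intrinsic"))
  expect_identical(propagate_damage(chain, out), out)

  out_c <- propagate_damage(chain, make_state(3, dead = 0L,
                                              cause = "coageing"))
  expect_equal(cause_of(out_c, c(1, 2)), c("coageing", "coageing"))
})

test_that("an exact half-and-half cause split propagates as intrinsic", {
  motif <- toy_network("two_dependee")
  st <- make_state(3, dead = c(0L, 1L), cause = c("intrinsic", "coageing"))
  out <- propagate_damage(motif, st)
  expect_equal(state_of(out, 2), "dysfunctional")
  expect_equal(cause_of(out, 2), "intrinsic")
})

test_that("network death is labelled by the majority node cause", {
  expect_equal(label_network_death(80, 15), "intrinsic")
  expect_equal(label_network_death(15, 80), "coageing")
  expect_equal(label_network_death(45, 45), "intrinsic")  # documented tie
  expect_equal(label_network_death(c(80, 15), c(15, 80)),
               c("intrinsic", "coageing"))
})

test_that("a single step behaves as forced in the degenerate regimes", {
  net <- grow_network(30, rng_seed = 1)
  quiet <- species_params(30, d = 0, r = 0, C = 0, f0 = 1)
  fresh <- make_state(30)

  # no damage source: state unchanged
  res <- step_pair(net, net, fresh, fresh, quiet, quiet, rng_seed = 1)
  expect_identical(res$state_A, fresh)
  expect_false(res$dead_A)

  # d = 1, r = 0: everything marked intrinsically in round one, dead at once
  lethal <- species_params(30, d = 1, r = 0, C = 0, f0 = 1)
  res <- step_pair(net, net, fresh, fresh, lethal, quiet, rng_seed = 1)
  expect_true(all(res$state_A$status == "dysfunctional"))
  expect_true(all(res$state_A$cause == "intrinsic"))
  expect_true(res$dead_A)
  expect_equal(label_network_death(res$counts$ns[1], res$counts$nc[1]),
               "intrinsic")

  # dead opponent (f_B = 0): alpha = C * 0, A receives no co-ageing damage
  coupled <- species_params(30, d = 0, r = 0, C = 1, f0 = 1)
  dead_B <- make_state(30, dead = 0:29)
  res <- step_pair(net, net, fresh, dead_B, coupled, quiet, rng_seed = 1)
  expect_identical(res$state_A, fresh)
})

test_that("node counts are conserved at every step of every pair", {
  pars <- ref_params()
  pa <- species_params(60, d = 0.004, r = 0.02, C = 0.02, f0 = 0.95)
  pb <- species_params(40, d = 0.01, r = 0.01, C = 0.01, f0 = 1)
  coh <- simulate_cohort(pa, pb, cohort_size = 100, max_steps = 2000,
                         master_seed = 3, record_trajectories = TRUE)
  tr <- coh$trajectory
  n_of <- ifelse(tr$species == "A", 60L, 40L)
  expect_true(all(tr$f + tr$ns + tr$nc == n_of))
  expect_true(all(tr$f >= 0 & tr$ns >= 0 & tr$nc >= 0))
})

test_that("an uncoupled pair member is bitwise identical to a solo run", {
  pars <- ref_params(C_A = 0)
  pair <- simulate_cohort(pars$A, pars$B, cohort_size = 50, max_steps = 3000,
                          master_seed = 11, record_trajectories = TRUE)
  solo <- simulate_cohort(pars$A, NULL, cohort_size = 50, max_steps = 3000,
                          master_seed = 11, record_trajectories = TRUE)
  a_pair <- dplyr::filter(pair$summary, species == "A")
  expect_identical(a_pair, solo$summary)

  # trajectories agree up to each individual's death (frozen rows after
  # death only exist while the partner is still alive)
  tp <- dplyr::inner_join(
    dplyr::filter(pair$trajectory, species == "A"),
    dplyr::transmute(a_pair, pair, end = death_time),
    by = "pair"
  )
  tp <- dplyr::filter(tp, t <= end)
  ts <- dplyr::filter(solo$trajectory, species == "A")
  expect_identical(dplyr::select(tp, pair, t, f, ns, nc),
                   dplyr::select(ts, pair, t, f, ns, nc))
})

test_that("perfect repair confers immortality", {
  p <- species_params(30, d = 0.5, r = 1, C = 0, f0 = 1)
  coh <- simulate_cohort(p, NULL, cohort_size = 30, max_steps = 300,
                         master_seed = 2)
  expect_true(all(coh$summary$censored))
})

test_that("single-node lifespans are geometric with success probability d", {
  p <- species_params(1, d = 0.3, r = 0, C = 0, f0 = 1, phi_T = 0.5)
  coh <- simulate_cohort(p, NULL, cohort_size = 3000, max_steps = 200,
                         master_seed = 4)
  dt <- coh$summary$death_time
  expect_true(all(!is.na(dt)))
  expect_true(all(coh$summary$death_cause == "intrinsic"))
  # mean 1/d = 3.33, SE = sqrt((1-d)/d^2 / n) ~ 0.051
  expect_lt(abs(mean(dt) - 1 / 0.3), 3 * sqrt((1 - 0.3) / 0.3^2 / 3000))
})

test_that("an overflowing co-ageing rate is clipped with a warning", {
  pa <- species_params(5, d = 0, r = 0, C = 300, f0 = 1)
  pb <- species_params(5, d = 0, r = 0, C = 0.1, f0 = 1)
  expect_warning(
    simulate_cohort(pa, pb, cohort_size = 2, max_steps = 10, master_seed = 1),
    regexp = "clipped"
  )
})

test_that("cohort simulation is reproducible given the master seed", {
  pars <- ref_params()
  a <- simulate_cohort(pars$A, pars$B, cohort_size = 40, max_steps = 2000,
                       master_seed = 9, record_trajectories = TRUE)
  b <- simulate_cohort(pars$A, pars$B, cohort_size = 40, max_steps = 2000,
                       master_seed = 9, record_trajectories = TRUE)
  expect_identical(a$summary, b$summary)
  expect_identical(a$trajectory, b$trajectory)
  c <- simulate_cohort(pars$A, pars$B, cohort_size = 40, max_steps = 2000,
                       master_seed = 10)
  expect_false(identical(a$summary, c$summary))
})

test_that("winner_continues = FALSE censors the survivor at first death", {
  cp <- chess_regime_params(20, C_white = 0.05, C_black = 0.08)
  coh <- simulate_cohort(cp$white, cp$black, cohort_size = 50,
                         max_steps = 2000, winner_continues = FALSE,
                         master_seed = 6)
  per_pair <- dplyr::count(dplyr::filter(coh$summary, !censored), pair)
  expect_true(all(per_pair$n == 1))
})
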