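archive_fixture <- function(path, seed = 9) {
  generate_pgn_archive(
    path, n_games = 120, white_elo = 1900, black_elo = 1800,
    white_rd = 40, black_rd = 40, win_prob = 0.75,
    n_draws = 12, n_forfeits = 8, n_timeouts = 6,
    n_missing_elo = 5, n_other_tc = 9, seed = seed
  )
}

test_that("the PGN reader recovers the archive's exact composition", {
  path <- withr::local_tempfile(fileext = ".pgn")
  truth <- archive_fixture(path)
  expect_message(games <- read_pgn_archive(path), "skipped 5")
  # all games except those missing rating tags
  expect_equal(nrow(games), sum(truth$has_elo_tags))
  expect_equal(attr(games, "n_skipped"), 5)
  parsable <- dplyr::filter(truth, has_elo_tags)
  expect_equal(games$result, parsable$result)
  expect_equal(games$termination, parsable$termination)
  expect_equal(games$time_control, parsable$time_control)
  expect_equal(games$length_turns, parsable$length_turns)
  # turn counting convention from raw plies
  expect_equal(games$length_turns, as.integer(ceiling(games$ply_count / 2)))
  expect_true(any(games$ply_count %% 2 == 1))  # odd-ply games exercised
  expect_true(all(games$white_rd == 40) && all(games$black_rd == 40))
})

test_that("archives are byte-identical across regenerations", {
  p1 <- withr::local_tempfile(fileext = ".pgn")
  p2 <- withr::local_tempfile(fileext = ".pgn")
  archive_fixture(p1)
  archive_fixture(p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("the RD default applies when no RD tags are present", {
  path <- withr::local_tempfile(fileext = ".pgn")
  writeLines(c(
    '[White "a"]', '[Black "b"]', '[Result "1-0"]',
    '[WhiteElo "1800"]', '[BlackElo "1700"]', '[TimeControl "300+0"]',
    "", "1. e4 e5 2. Nf3 1-0", ""
  ), path)
  g <- read_pgn_archive(path, rd_default = 75)
  expect_equal(g$white_rd, 75)
  expect_equal(g$ply_count, 3L)
  expect_equal(g$length_turns, 2L)  # ceil(3 / 2)
  expect_error(read_pgn_archive(withr::local_tempfile()), "cannot read")
})

test_that("filtering enforces the expected-outcome band and exclusions", {
  path <- withr::local_tempfile(fileext = ".pgn")
  truth <- archive_fixture(path)
  games <- suppressMessages(read_pgn_archive(path))
  e <- expected_outcome(1900, 1800, 40, 40)  # ~0.637 for every game

  kept <- filter_games(games, e_low = 0.55, e_high = 0.70)
  # exactly the decisive, normally-terminated, 300 s games
  expect_equal(nrow(kept), 120)
  expect_true(all(kept$result != "draw"))
  expect_true(all(!kept$termination %in% c("forfeit", "timeout")))
  expect_true(all(kept$time_control == 300))
  expect_true(all(kept$e_white >= 0.55 & kept$e_white <= 0.70))

  # idempotent and order-preserving
  again <- filter_games(kept, e_low = 0.55, e_high = 0.70)
  expect_identical(again, kept)

  # a band that misses the archive's expected outcome keeps nothing
  expect_equal(nrow(filter_games(games, e_low = 0.75, e_high = 0.85)), 0)
  expect_error(filter_games(games, e_low = 0.8, e_high = 0.7), "e_low")

  # the empirical white win rate matches the generating probability
  p_hat <- mean(kept$result == "white_win")
  expect_lt(abs(p_hat - 0.75), 3 * sqrt(0.75 * 0.25 / nrow(kept)))
})

test_that("per-color demography kills the loser and censors the winner", {
  games <- tibble::tibble(
    game_id = 1:10, white_elo = 1900, black_elo = 1800,
    white_rd = 40, black_rd = 40,
    result = "white_win", termination = "other",
    time_control = 300, ply_count = 60L, length_turns = 30L
  )
  dem <- games_to_demography(games)
  black <- dplyr::filter(dem, color == "black")
  white <- dplyr::filter(dem, color == "white")
  expect_equal(black$mu[black$t == 30], 1)
  expect_true(all(white$mu == 0))
  expect_true(all(white$S == 10))
  expect_error(games_to_demography(games[0, ]), "empty")
})

test_that("survivor accounting closes on a mixed archive", {
  path <- withr::local_tempfile(fileext = ".pgn")
  archive_fixture(path)
  games <- suppressMessages(read_pgn_archive(path))
  kept <- filter_games(games, e_low = 0.55, e_high = 0.70)
  dem <- games_to_demography(kept)
  for (col in c("white", "black")) {
    d <- dplyr::filter(dem, color == col)
    expect_equal(d$S[1], nrow(kept))
    expect_identical(d$S - d$deaths,
                     c(d$S[-1], d$S[nrow(d)] - d$deaths[nrow(d)]))
  }
  # every game kills exactly one color
  total_deaths <- sum(dem$deaths)
  expect_equal(total_deaths, nrow(kept))
})

test_that("the chess regime pins the damage-free parameter restrictions", {
  cp <- chess_regime_params(24, C_white = 0.02, C_black = 0.03)
  for (side in cp) {
    expect_equal(side$d, 0)
    expect_equal(side$r, 0)
    expect_equal(side$f0, 1)
    expect_equal(side$n_nodes, 24L)
    expect_equal(side$phi_T, 0.15)
  }
  expect_lt(cp$white$C, cp$black$C)  # stronger white receives less damage
})
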