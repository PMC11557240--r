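# Mapping of PGN Termination tag text onto the coarse termination classes
# used for filtering.  "Time forfeit" is classed as timeout; plain
# "forfeit"/"abandoned" as forfeit; unrecognized values as "other".
classify_termination <- function(x) {
  x <- tolower(ifelse(is.na(x), "", x))
  dplyr::case_when(
    grepl("mate", x) ~ "checkmate",
    grepl("resign", x) ~ "resign",
    grepl("time", x) ~ "timeout",
    grepl("forfeit|abandon", x) ~ "forfeit",
    x %in% c("checkmate", "resign", "forfeit", "timeout") ~ x,
    TRUE ~ "other"
  )
}

parse_time_control <- function(x) {
  base <- suppressWarnings(as.integer(sub("\\+.*$", "", x)))
  base
}

#' Read a PGN chess archive
#'
#' Parses a standard PGN file (tag-pair sections plus movetext) into one
#' record per game.  Games missing a `WhiteElo` or `BlackElo` tag, or with
#' an unknown (`*`) result, are skipped; the skip count is reported via a
#' message and the `n_skipped` attribute.  Rating deviations are taken from
#' `WhiteRD`/`BlackRD` tags when present (the FICS dialect) and otherwise
#' default to `rd_default`.  Game length is counted in full moves (turns):
#' `length_turns = ceiling(ply / 2)`.
#'
#' @param path Path to a PGN file.
#' @param rd_default Rating deviation (Elo points) assumed when no RD tag is
#'   present (default 50).
#' @return A tibble with one row per parsable game: `game_id`, `white_elo`,
#'   `white_rd`, `black_elo`, `black_rd`, `result` (`"white_win"`,
#'   `"black_win"`, `"draw"`), `termination`, `time_control` (base seconds),
#'   `ply_count`, `length_turns`.
#' @export
read_pgn_archive <- function(path, rd_default = 50) {
  if (!file.exists(path)) abort(sprintf("cannot read PGN file: %s", path))
  lines <- readLines(path, warn = FALSE)
  games <- split_pgn_games(lines)
  if (length(games) == 0) abort("no games found in PGN file")

  n_skipped <- 0L
  rows <- list()
  for (g in games) {
    tags <- g$tags
    res_tag <- tags[["Result"]]
    result <- switch(res_tag %||% "*",
                     "1-0" = "white_win", "0-1" = "black_win",
                     "1/2-1/2" = "draw", NA_character_)
    we <- suppressWarnings(as.numeric(tags[["WhiteElo"]]))
    be <- suppressWarnings(as.numeric(tags[["BlackElo"]]))
    if (is.na(result) || length(we) == 0 || length(be) == 0 ||
        is.na(we) || is.na(be)) {
      n_skipped <- n_skipped + 1L
      next
    }
    ply <- g$ply
    if (ply == 0 && !is.null(tags[["PlyCount"]])) {
      ply <- suppressWarnings(as.integer(tags[["PlyCount"]]))
      if (is.na(ply)) ply <- 0L
    }
    if (ply < 1) {
      n_skipped <- n_skipped + 1L
      next
    }
    wrd <- suppressWarnings(as.numeric(tags[["WhiteRD"]]))
    brd <- suppressWarnings(as.numeric(tags[["BlackRD"]]))
    rows[[length(rows) + 1]] <- tibble(
      white_elo = we, black_elo = be,
      white_rd = if (length(wrd) && !is.na(wrd)) wrd else rd_default,
      black_rd = if (length(brd) && !is.na(brd)) brd else rd_default,
      result = result,
      termination = classify_termination(tags[["Termination"]] %||% NA),
      time_control = parse_time_control(tags[["TimeControl"]] %||% NA),
      ply_count = as.integer(ply),
      length_turns = as.integer(ceiling(ply / 2))
    )
  }
  if (length(rows) == 0) abort("no parsable games in PGN file")
  out <- bind_rows(rows)
  out <- mutate(out, game_id = dplyr::row_number(), .before = 1)
  if (n_skipped > 0) {
    inform(sprintf("skipped %d game(s) missing required tags", n_skipped))
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Split raw PGN lines into games; returns a list of
# list(tags = named list, ply = movetext ply count).
split_pgn_games <- function(lines) {
  games <- list()
  tags <- list()
  movetok <- character(0)
  in_moves <- FALSE
  flush <- function() {
    if (length(tags) || length(movetok)) {
      games[[length(games) + 1]] <<- list(tags = tags,
                                          ply = count_ply(movetok))
    }
    tags <<- list()
    movetok <<- character(0)
    in_moves <<- FALSE
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "") next
    m <- regmatches(ln, regexec('^\\[(\\w+)\\s+"(.*)"\\]$', ln))[[1]]
    if (length(m) == 3) {
      if (in_moves) flush()
      tags[[m[2]]] <- m[3]
    } else {
      in_moves <- TRUE
      movetok <- c(movetok, strsplit(ln, "\\s+")[[1]])
    }
  }
  flush()
  games
}

count_ply <- function(tok) {
  if (length(tok) == 0) return(0L)
  # strip {comments}
  drop <- logical(length(tok))
  depth <- 0L
  for (i in seq_along(tok)) {
    if (grepl("^\\{", tok[i])) depth <- depth + 1L
    if (depth > 0) drop[i] <- TRUE
    if (grepl("\\}$", tok[i])) depth <- max(0L, depth - 1L)
  }
  tok <- tok[!drop]
  is_move <- !grepl("^\\d+\\.+$", tok) &           # move numbers
    !tok %in% c("1-0", "0-1", "1/2-1/2", "*") &    # results
    !grepl("^\\$\\d+$", tok) &                     # NAGs
    !grepl("^[()]+$", tok)
  # "1.e4" style: number glued to the move
  glued <- grepl("^\\d+\\.+\\S", tok)
  sum(is_move | glued)
}

#' Filter a chess archive for demographic analysis
#'
#' Keeps games whose Glicko expected outcome for white lies in
#' `[e_low, e_high]`, whose base time control matches, whose result is not a
#' draw, and whose termination is not in the excluded set (forfeit-like
#' endings, including time forfeits, are excluded by default).  Filtering is
#' order-preserving and idempotent.
#'
#' @param games A game tibble from [read_pgn_archive()].
#' @param e_low,e_high Expected-outcome band, `0 <= e_low < e_high <= 1`.
#' @param time_control Required base time in seconds (default 300, i.e. a
#'   5-minute game); `NULL` disables the time-control filter.
#' @param exclude Termination classes to drop.
#' @return The filtered tibble, with an `e_white` column added.
#' @export
filter_games <- function(games, e_low = 0.7, e_high = 0.8,
                         time_control = 300,
                         exclude = c("forfeit", "timeout")) {
  if (!(e_low >= 0 && e_low < e_high && e_high <= 1)) {
    abort("need 0 <= e_low < e_high <= 1")
  }
  out <- games
  if (!("e_white" %in% names(out))) {
    out <- mutate(out, e_white = expected_outcome(
      .data$white_elo, .data$black_elo, .data$white_rd, .data$black_rd))
  }
  out <- filter(out,
                .data$e_white >= e_low, .data$e_white <= e_high,
                .data$result != "draw",
                !(.data$termination %in% exclude))
  if (!is.null(time_control)) {
    out <- filter(out, !is.na(.data$time_control),
                  .data$time_control == !!time_control)
  }
  out
}

#' Per-color survival demography of chess games
#'
#' Treats each game as a pair of co-ageing cohorts: the losing color "dies"
#' at the game's length in turns, while the winning color is
#' censored-alive forever (the winner-continues convention), so
#' `S_color(t)` counts the players of that color still playing at turn `t`
#' or already won.
#'
#' @param games A (typically filtered) game tibble.
#' @param max_t Last turn of the table; defaults to the longest game.
#' @return A tibble of per-color hazard tables: `color`, `t`, `S`, `deaths`,
#'   `mu`.
#' @export
games_to_demography <- function(games, max_t = NULL) {
  if (is.null(games) || nrow(games) == 0) {
    abort("empty game list; filter produced no games")
  }
  if (is.null(max_t)) max_t <- max(games$length_turns)
  death_of <- function(loser_result) {
    ifelse(games$result == loser_result, games$length_turns, NA_integer_)
  }
  bind_rows(
    mutate(hazard_curve(death_of("black_win"), max_t), color = "white",
           .before = 1),
    mutate(hazard_curve(death_of("white_win"), max_t), color = "black",
           .before = 1)
  )
}

#' Generate a synthetic PGN archive
#'
#' Writes a deterministic, fully synthetic PGN file with controlled
#' composition, so the whole chess pipeline can be exercised without any
#' external download.  Decisive games are won by white with probability
#' `win_prob`; game lengths are drawn from a truncated normal in plies.
#' Additional games with draws, forfeit-like terminations, a different time
#' control, or missing Elo tags can be appended in known numbers.
#'
#' @param path Output file path.
#' @param n_games Number of "clean" decisive games at the main time control.
#' @param white_elo,black_elo Mean Elo ratings of the two sides.
#' @param elo_sd Player-to-player rating spread (SD in Elo points).
#' @param white_rd,black_rd Rating deviations written as `WhiteRD`/`BlackRD`
#'   tags.
#' @param win_prob Probability that white wins a decisive game.
#' @param mean_ply,sd_ply Game length distribution in plies (truncated at 10).
#' @param time_control Base seconds written to the `TimeControl` tag.
#' @param n_draws,n_forfeits,n_timeouts,n_missing_elo,n_other_tc Counts of
#'   additional games of each special kind.
#' @param seed Integer seed; the file is byte-identical across runs with the
#'   same arguments.
#' @return Invisibly, a tibble describing every game written (the ground
#'   truth for tests), with a `category` column.
#' @export
generate_pgn_archive <- function(path, n_games = 200,
                                 white_elo = 1900, black_elo = 1700,
                                 elo_sd = 0, white_rd = 50, black_rd = 50,
                                 win_prob = 0.75, mean_ply = 60, sd_ply = 15,
                                 time_control = 300,
                                 n_draws = 0, n_forfeits = 0, n_timeouts = 0,
                                 n_missing_elo = 0, n_other_tc = 0,
                                 seed = 1) {
  with_local_seed(seed, {
    specs <- list(
      list(n = n_games, category = "clean", tc = time_control,
           term = "Normal", decisive = TRUE, elo = TRUE),
      list(n = n_draws, category = "draw", tc = time_control,
           term = "Normal", decisive = FALSE, elo = TRUE),
      list(n = n_forfeits, category = "forfeit", tc = time_control,
           term = "Abandoned", decisive = TRUE, elo = TRUE),
      list(n = n_timeouts, category = "timeout", tc = time_control,
           term = "Time forfeit", decisive = TRUE, elo = TRUE),
      list(n = n_other_tc, category = "other_tc", tc = time_control * 2,
           term = "Normal", decisive = TRUE, elo = TRUE),
      list(n = n_missing_elo, category = "missing_elo", tc = time_control,
           term = "Normal", decisive = TRUE, elo = FALSE)
    )
    vocab <- c("e4", "d4", "Nf3", "c4", "g3", "Bg2", "O-O", "Re1", "Qc2",
               "Nc3", "d5", "Nf6", "e6", "Be7", "b6", "Bb7", "h6", "a4")
    out_lines <- character(0)
    truth <- list()
    gid <- 0L
    for (sp in specs) {
      if (sp$n == 0) next
      for (k in seq_len(sp$n)) {
        gid <- gid + 1L
        we <- round(white_elo + if (elo_sd > 0) rnorm(1, 0, elo_sd) else 0)
        be <- round(black_elo + if (elo_sd > 0) rnorm(1, 0, elo_sd) else 0)
        ply <- max(10L, round(rnorm(1, mean_ply, sd_ply)))
        result <- if (!sp$decisive) {
          "1/2-1/2"
        } else if (runif(1) < win_prob) "1-0" else "0-1"
        tags <- c(
          sprintf('[Event "synthetic game %d"]', gid),
          sprintf('[White "white_%d"]', gid),
          sprintf('[Black "black_%d"]', gid),
          sprintf('[Result "%s"]', result),
          if (sp$elo) sprintf('[WhiteElo "%d"]', we),
          if (sp$elo) sprintf('[BlackElo "%d"]', be),
          sprintf('[WhiteRD "%.1f"]', white_rd),
          sprintf('[BlackRD "%.1f"]', black_rd),
          sprintf('[TimeControl "%d+0"]', sp$tc),
          sprintf('[Termination "%s"]', sp$term),
          sprintf('[PlyCount "%d"]', ply)
        )
        moves <- sample(vocab, ply, replace = TRUE)
        mt <- character(0)
        for (mv in seq_len(ceiling(ply / 2))) {
          w <- moves[2 * mv - 1]
          b <- if (2 * mv <= ply) moves[2 * mv] else NULL
          mt <- c(mt, paste0(mv, "."), w, b)
        }
        mt <- c(mt, result)
        body <- paste(strwrap(paste(mt, collapse = " "), width = 78),
                      collapse = "\n")
        out_lines <- c(out_lines, tags, "", body, "")
        truth[[gid]] <- tibble(
          game_id = gid, category = sp$category,
          white_elo = we, black_elo = be,
          white_rd = white_rd, black_rd = black_rd,
          result = switch(result, "1-0" = "white_win", "0-1" = "black_win",
                          "1/2-1/2" = "draw"),
          termination = classify_termination(sp$term),
          time_control = sp$tc, ply_count = as.integer(ply),
          length_turns = as.integer(ceiling(ply / 2)),
          has_elo_tags = sp$elo
        )
      }
    }
    writeLines(out_lines, path)
    invisible(bind_rows(truth))
  })
}
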