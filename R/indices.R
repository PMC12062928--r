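#' Play Asymmetry Index
#'
#' Signed imbalance of directed offensive and defensive patterns between two
#' players, relative to all patterns in the window:
#' `PAI = [(off A->B + def B->A) - (off B->A + def A->B)] / (off + def + neutral)`.
#' The denominator counts every pattern in the window (both players,
#' solitary/neutral included). Values near +1 indicate complete asymmetry in
#' favor of player A, near -1 in favor of player B, near 0 symmetric play.
#'
#' @param patterns Tibble of pattern events with `actor`, `target`,
#'   `category` columns.
#' @param player_a,player_b The two players; `player_a` carries the positive
#'   orientation.
#' @return A number in `[-1, 1]`, or `NA` for an empty window.
#' @export
pai <- function(patterns, player_a, player_b) {
  if (player_a == player_b) abort("players must differ")
  n <- nrow(patterns)
  if (n == 0) return(NA_real_)
  off <- patterns$category == "offensive"
  def <- patterns$category == "defensive"
  a2b <- patterns$actor == player_a & !is.na(patterns$target) & patterns$target == player_b
  b2a <- patterns$actor == player_b & !is.na(patterns$target) & patterns$target == player_a
  num <- (sum(off & a2b) + sum(def & b2a)) - (sum(off & b2a) + sum(def & a2b))
  num / n
}

#' Shannon diversity of play patterns
#'
#' Natural-log Shannon index `H' = -sum(p_i * ln p_i)` over pattern-type
#' frequencies, where a type is a pattern name (not its category). Measures
#' the variability of play within a window or session; 0 for a single
#' repeated pattern, `ln(k)` for `k` distinct patterns used once each.
#'
#' @param patterns Tibble of pattern events with a `pattern` column, or a
#'   character vector of pattern names.
#' @return `H' >= 0`, or `NA` for empty input.
#' @export
shannon_index <- function(patterns) {
  x <- if (is.data.frame(patterns)) patterns$pattern else patterns
  x <- norm_pattern(x)
  if (length(x) == 0) return(NA_real_)
  p <- tabulate(factor(x)) / length(x)
  -sum(p * log(p))
}

#' Focal events for the sequential analysis
#'
#' Derives the focal events around which before/after windows are cut: each
#' stimulus record that was not itself the response half of a mimicry pair
#' becomes a focal event, labelled `PF_not_mim` / `FPF_not_mim` when
#' unreplicated and `PF_RFM` / `FPF_RFM` when replicated (the focal position
#' of a mimicry event is the stimulus onset).
#'
#' @param records Stimulus records from [detect_rfm()].
#' @return Tibble: `session_id`, `focal_id`, `kind`, `expr_type`, `onset`,
#'   `replicated`.
#' @export
focal_events <- function(records) {
  r <- records[!records$is_response, ]
  tibble::tibble(
    session_id = r$session_id,
    focal_id = r$stimulus_id,
    kind = paste0(r$expr_type, ifelse(r$replicated, "_RFM", "_not_mim")),
    expr_type = r$expr_type,
    onset = r$onset,
    replicated = r$replicated
  )
}

#' Cut before/after pattern windows around focal events
#'
#' For each retained focal event, collects up to `k` pattern events strictly
#' before and strictly after the focal onset. Events with an empty side
#' yield no windows and are dropped first; among the rest, consecutive focal
#' events are both retained only when at least `2 * k + min_separation`
#' patterns lie between them (the separation requirement excludes the
#' patterns consumed by the two windows) — a too-close event is dropped and
#' the spacing is then measured from the last retained one. Events with at
#' least one pattern on each side are kept even when a side is shorter than
#' `k`.
#'
#' @param events Validated event tibble.
#' @param focal Tibble from [focal_events()] (columns `session_id`,
#'   `focal_id`, `kind`, `onset`).
#' @param k Window size in patterns (default 4).
#' @param min_separation Extra patterns required between the two windows of
#'   consecutive retained events (default 4).
#' @return Tibble with one row per retained focal event: identifiers,
#'   session players and initiator, `n_before`, `n_after`, and list-columns
#'   `before` / `after` holding the pattern-event tibbles.
#' @export
extract_windows <- function(events, focal, k = 4, min_separation = 4) {
  pat <- events[events$event_kind == "pattern",
                c("session_id", "time_s", "actor", "target", "pattern",
                  "category"), drop = FALSE]
  need_between <- 2 * k + min_separation
  pat_by_session <- split(seq_len(nrow(pat)), pat$session_id)
  by_session <- split(seq_len(nrow(focal)), focal$session_id)
  keep_idx <- integer(0)
  n_before <- integer(0)
  n_after <- integer(0)
  initiator <- character(0)
  before <- list()
  after <- list()
  for (s in seq_along(by_session)) {
    fi <- by_session[[s]][order(focal$onset[by_session[[s]]])]
    sid <- focal$session_id[fi[1]]
    prows <- pat_by_session[[sid]]
    if (is.null(prows)) next
    p <- pat[prows, , drop = FALSE]
    pt <- p$time_s
    init_s <- p$actor[which.min(pt)]
    # events with an empty side yield no windows and do not take part in the
    # spacing chain
    fi <- fi[vapply(fi, function(i) {
      any(pt < focal$onset[i]) && any(pt > focal$onset[i])
    }, logical(1))]
    last_onset <- -Inf
    for (j in seq_along(fi)) {
      i <- fi[j]
      onset <- focal$onset[i]
      if (!is.infinite(last_onset) &&
          sum(pt > last_onset & pt < onset) < need_between) next
      last_onset <- onset
      before_idx <- utils::tail(which(pt < onset), k)
      after_idx <- utils::head(which(pt > onset), k)
      keep_idx <- c(keep_idx, i)
      n_before <- c(n_before, length(before_idx))
      n_after <- c(n_after, length(after_idx))
      initiator <- c(initiator, init_s)
      before[[length(before) + 1L]] <- p[before_idx, , drop = FALSE]
      after[[length(after) + 1L]] <- p[after_idx, , drop = FALSE]
    }
  }
  players <- events[match(focal$session_id[keep_idx], events$session_id),
                    c("player_a", "player_b"), drop = FALSE]
  tibble::tibble(
    session_id = focal$session_id[keep_idx],
    focal_id = focal$focal_id[keep_idx],
    kind = focal$kind[keep_idx],
    onset = focal$onset[keep_idx],
    player_a = players$player_a,
    player_b = players$player_b,
    initiator = initiator,
    n_before = n_before,
    n_after = n_after,
    before = before,
    after = after
  )
}

#' Asymmetry and diversity indices before and after focal events
#'
#' Computes `pai_before`, `pai_after`, `h_before` and `h_after` for each
#' window pair by delegating to [pai()] and [shannon_index()]. PAI is
#' oriented by the session initiator (the first pattern-performer carries
#' the positive sign) unless `orientation = "as_recorded"`, which uses the
#' log's `player_a`.
#'
#' @param windows Tibble from [extract_windows()].
#' @param orientation `"initiator"` (default) or `"as_recorded"`.
#' @return `windows` with the four index columns appended (list-columns
#'   dropped).
#' @export
before_after_indices <- function(windows, orientation = c("initiator", "as_recorded")) {
  orientation <- match.arg(orientation)
  a <- if (orientation == "initiator") windows$initiator else windows$player_a
  b <- ifelse(a == windows$player_a, windows$player_b, windows$player_a)
  n <- nrow(windows)
  pai_b <- pai_a <- h_b <- h_a <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    pai_b[i] <- pai(windows$before[[i]], a[i], b[i])
    pai_a[i] <- pai(windows$after[[i]], a[i], b[i])
    h_b[i] <- shannon_index(windows$before[[i]])
    h_a[i] <- shannon_index(windows$after[[i]])
  }
  out <- windows[setdiff(names(windows), c("before", "after"))]
  out$orientation <- orientation
  out$pai_before <- pai_b
  out$pai_after <- pai_a
  out$h_before <- h_b
  out$h_after <- h_a
  out
}
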