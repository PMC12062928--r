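LOG_COLUMNS <- c("session_id", "group", "player_a", "player_b", "event_kind",
                 "time_s", "offset_s", "actor", "target", "pattern",
                 "expr_type", "perception")

PERCEPTION_LEVELS <- c("frontal", "lateral", "blind", "unknown")

#' Load a play-session event log
#'
#' Reads a long-format tab-separated event log (one row per behavioral
#' pattern or facial-expression event), validates it against an ethogram and
#' returns a tidy event tibble. Within each session events are sorted by
#' time, with ties broken by file order; times are seconds from session
#' start (0-based) and the session end is taken as the latest event time or
#' expression offset.
#'
#' Required columns: `session_id`, `group`, `player_a`, `player_b`,
#' `event_kind` (`pattern`/`expression`), `time_s`, `offset_s` (blank for
#' patterns), `actor`, `target` (blank for solitary patterns), `pattern`,
#' `expr_type` (`PF`/`FPF`, blank for patterns), `perception` (`frontal`,
#' `lateral`, `blind`, `unknown`; blank for patterns).
#'
#' @param path Path to the TSV event log.
#' @param ethogram Ethogram tibble from [load_ethogram()]; pattern rows with
#'   patterns outside it are rejected with row numbers.
#' @return Event tibble with an additional `category` column on pattern rows.
#' @export
load_sessions <- function(path, ethogram) {
  if (!file.exists(path)) abort(paste0("event log not found: ", path))
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      time_s = readr::col_double(), offset_s = readr::col_double(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
  missing_cols <- setdiff(LOG_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("event log is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  validate_sessions(raw[LOG_COLUMNS], ethogram)
}

#' Validate an in-memory event log
#'
#' Applies the same checks as [load_sessions()] to an already-constructed
#' event tibble (e.g. from [simulate_play()]), attaching pattern categories.
#'
#' @param events Event tibble with the event-log columns.
#' @param ethogram Ethogram tibble.
#' @return The validated, time-sorted event tibble with `category` attached.
#' @export
validate_sessions <- function(events, ethogram) {
  ev <- tibble::as_tibble(events)
  bad_kind <- which(!ev$event_kind %in% c("pattern", "expression"))
  if (length(bad_kind) > 0) abort_rows("event_kind must be 'pattern' or 'expression'", bad_kind)
  bad_time <- which(!is.finite(ev$time_s) | ev$time_s < 0)
  if (length(bad_time) > 0) abort_rows("time_s must be a non-negative number", bad_time)

  is_expr <- ev$event_kind == "expression"
  bad_off <- which(is_expr & (!is.finite(ev$offset_s) | ev$offset_s < ev$time_s))
  if (length(bad_off) > 0) abort_rows("expression offset_s must be >= time_s", bad_off)
  bad_type <- which(is_expr & !ev$expr_type %in% c("PF", "FPF"))
  if (length(bad_type) > 0) abort_rows("expression expr_type must be PF or FPF", bad_type)
  bad_perc <- which(is_expr & !ev$perception %in% PERCEPTION_LEVELS)
  if (length(bad_perc) > 0) {
    abort_rows(paste0("perception must be one of ",
                      paste(PERCEPTION_LEVELS, collapse = "/")), bad_perc)
  }

  bad_actor <- which(!(ev$actor == ev$player_a | ev$actor == ev$player_b))
  if (length(bad_actor) > 0) abort_rows("actor must be player_a or player_b", bad_actor)
  bad_self <- which(!is.na(ev$target) & ev$target == ev$actor)
  if (length(bad_self) > 0) abort_rows("actor and target must differ", bad_self)
  bad_target <- which(!is.na(ev$target) &
                        !(ev$target == ev$player_a | ev$target == ev$player_b))
  if (length(bad_target) > 0) abort_rows("target must be a session player or blank", bad_target)
  bad_players <- which(ev$player_a == ev$player_b)
  if (length(bad_players) > 0) abort_rows("sessions need two distinct players", bad_players)

  consistent <- dplyr::summarise(
    dplyr::group_by(ev, .data$session_id),
    ok = dplyr::n_distinct(.data$group) == 1 &&
      dplyr::n_distinct(.data$player_a) == 1 &&
      dplyr::n_distinct(.data$player_b) == 1,
    .groups = "drop"
  )
  if (any(!consistent$ok)) {
    abort(paste0("inconsistent group/player columns within session(s): ",
                 paste(consistent$session_id[!consistent$ok], collapse = ", ")))
  }

  ev$category <- NA_character_
  is_pat <- ev$event_kind == "pattern"
  if (any(is_pat)) {
    ev$pattern[is_pat] <- norm_pattern(ev$pattern[is_pat])
    ev$category[is_pat] <- pattern_category(ethogram, ev$pattern[is_pat])
  }

  ev$.file_order <- seq_len(nrow(ev))
  ev <- dplyr::arrange(ev, .data$session_id, .data$time_s, .data$.file_order)
  ev$.file_order <- NULL
  ev
}

#' Write a play-session event log
#'
#' Inverse of [load_sessions()]: writes the canonical tab-separated columns
#' so that a write/read round trip is the identity on the data model.
#'
#' @param events Validated event tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(events, path) {
  readr::write_tsv(events[LOG_COLUMNS], path, progress = FALSE)
  invisible(path)
}

#' Per-session summary of an event log
#'
#' @param events Validated event tibble.
#' @return One row per session: players, group, `start` (0), `end` (latest
#'   event time or expression offset), `duration`, event counts.
#' @export
session_table <- function(events) {
  dplyr::summarise(
    dplyr::group_by(events, .data$session_id),
    group = .data$group[1],
    player_a = .data$player_a[1],
    player_b = .data$player_b[1],
    start = 0,
    end = max(c(.data$time_s, .data$offset_s), na.rm = TRUE),
    duration = .data$end - .data$start,
    n_patterns = sum(.data$event_kind == "pattern"),
    n_expressions = sum(.data$event_kind == "expression"),
    .groups = "drop"
  )
}

#' Session-duration descriptive statistics
#'
#' Mean, standard error (sd/sqrt(n)), minimum and maximum of session
#' durations in seconds. With a single session the SE is reported as `NA`.
#'
#' @param events Validated event tibble (or a [session_table()] result).
#' @return A one-row tibble: `n`, `mean`, `se`, `min`, `max`.
#' @export
session_duration_stats <- function(events) {
  st <- if ("duration" %in% names(events)) events else session_table(events)
  if (nrow(st) == 0) abort("no sessions")
  d <- st$duration
  tibble::tibble(
    n = length(d),
    mean = mean(d),
    se = if (length(d) > 1) sd(d) / sqrt(length(d)) else NA_real_,
    min = min(d),
    max = max(d)
  )
}

#' Per-individual play-face rates
#'
#' Divides each individual's play-face counts by the number of play sessions
#' they took part in. Individuals with zero sessions either keep a rate of 0
#' (`zero_convention = "zero"`, the default, matching whole-group means) or
#' are dropped (`"exclude"`).
#'
#' @param summaries Tibble with columns `n_sessions`, `n_pf`, `n_fpf` (e.g.
#'   [group_composition()]).
#' @param zero_convention `"zero"` or `"exclude"`.
#' @return `summaries` with `pf_rate` and `fpf_rate` columns appended.
#' @export
#' @examples
#' rates_per_session(group_composition())
rates_per_session <- function(summaries, zero_convention = c("zero", "exclude")) {
  zero_convention <- match.arg(zero_convention)
  need <- c("n_sessions", "n_pf", "n_fpf")
  missing_cols <- setdiff(need, names(summaries))
  if (length(missing_cols) > 0) {
    abort(paste0("summaries missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  neg <- which(summaries$n_sessions < 0 | summaries$n_pf < 0 | summaries$n_fpf < 0)
  if (length(neg) > 0) abort_rows("counts must be non-negative", neg)
  out <- tibble::as_tibble(summaries)
  if (zero_convention == "exclude") out <- out[out$n_sessions > 0, ]
  zero <- out$n_sessions == 0
  out$pf_rate <- ifelse(zero, 0, out$n_pf / out$n_sessions)
  out$fpf_rate <- ifelse(zero, 0, out$n_fpf / out$n_sessions)
  out
}

#' Packaged study-group composition table
#'
#' Per-individual observation summary for the two captive lowland-gorilla
#' family groups (VDS and BEA): sex, age class, age, hours observed, number
#' of play sessions, and counts of play faces (PF) and full play faces
#' (FPF) performed.
#'
#' @return A tibble with one row per individual.
#' @export
group_composition <- function() {
  readr::read_tsv(
    system.file("extdata", "group_composition.tsv",
                package = "playmimicry", mustWork = TRUE),
    col_types = readr::cols(
      subject = readr::col_character(), sex = readr::col_character(),
      age_class = readr::col_character(), group = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
}
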