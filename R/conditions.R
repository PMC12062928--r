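SESSION_CONDITIONS <- c("PF_not_mim", "FPF_not_mim", "PF_RFM", "FPF_RFM",
                        "PF_and_FPF_RFM", "excluded")

#' Classify sessions into the five mimicry conditions
#'
#' Each session receives exactly one label: `PF_and_FPF_RFM` when mimicry of
#' both expression types occurred, `FPF_RFM` / `PF_RFM` when mimicry of only
#' one type occurred, `PF_not_mim` when no mimicry occurred and the players
#' performed at least two unreplicated PFs with no FPF at all in the session
#' (`FPF_not_mim` symmetrically), and `excluded` otherwise — sessions
#' without expressions and ambiguous sessions mixing unreplicated PFs and
#' FPFs. `first_event_time` is the onset of the first qualifying event: the
#' first unreplicated expression for the not-mimicked conditions, the first
#' mimicry stimulus for the RFM conditions (the earlier of the two types for
#' mixed sessions).
#'
#' @param events Validated event tibble.
#' @param records Stimulus records from [detect_rfm()] on the same log.
#' @param first_event For the RFM conditions, whether `first_event_time` is
#'   the first mimicry stimulus onset (`"first_rfm"`, default — the
#'   comparison targets mimicry's effect) or the first expression of any
#'   kind (`"first_expression"`, which makes the timing origin comparable
#'   across all five conditions).
#' @return Tibble: `session_id`, `condition`, `first_event_time` (`NA` when
#'   excluded).
#' @export
classify_condition <- function(events, records,
                               first_event = c("first_rfm", "first_expression")) {
  first_event <- match.arg(first_event)
  sids <- unique(events$session_id)
  rec_by_session <- split(seq_len(nrow(records)), records$session_id)
  condition <- character(length(sids))
  t0 <- numeric(length(sids))
  for (ii in seq_along(sids)) {
    r <- records[rec_by_session[[sids[ii]]] %||% integer(0), , drop = FALSE]
    pf_rfm <- r$replicated & r$expr_type == "PF"
    fpf_rfm <- r$replicated & r$expr_type == "FPF"
    n_pf <- sum(r$expr_type == "PF")
    n_fpf <- sum(r$expr_type == "FPF")
    if (any(pf_rfm) && any(fpf_rfm)) {
      condition[ii] <- "PF_and_FPF_RFM"
      t0[ii] <- if (first_event == "first_rfm") min(r$onset[pf_rfm | fpf_rfm])
                else min(r$onset)
    } else if (any(fpf_rfm)) {
      condition[ii] <- "FPF_RFM"
      t0[ii] <- if (first_event == "first_rfm") min(r$onset[fpf_rfm])
                else min(r$onset)
    } else if (any(pf_rfm)) {
      condition[ii] <- "PF_RFM"
      t0[ii] <- if (first_event == "first_rfm") min(r$onset[pf_rfm])
                else min(r$onset)
    } else if (n_pf >= 2 && n_fpf == 0) {
      condition[ii] <- "PF_not_mim"
      t0[ii] <- min(r$onset[r$expr_type == "PF"])
    } else if (n_fpf >= 2 && n_pf == 0) {
      condition[ii] <- "FPF_not_mim"
      t0[ii] <- min(r$onset[r$expr_type == "FPF"])
    } else {
      condition[ii] <- "excluded"
      t0[ii] <- NA_real_
    }
  }
  tibble::tibble(session_id = sids, condition = condition,
                 first_event_time = t0)
}

#' Time remaining from the first qualifying event to session end
#'
#' For every non-excluded session, the seconds between the first qualifying
#' expression or mimicry event (see [classify_condition()]) and the end of
#' the session. Excluded sessions get `NA`.
#'
#' @param events Validated event tibble.
#' @param conditions Output of [classify_condition()].
#' @return `conditions` with a `time_remaining` column appended.
#' @export
time_remaining <- function(events, conditions) {
  st <- session_table(events)
  out <- dplyr::left_join(conditions, st[, c("session_id", "end", "duration")],
                          by = "session_id")
  out$time_remaining <- ifelse(out$condition == "excluded", NA_real_,
                               out$end - out$first_event_time)
  out[, c("session_id", "condition", "first_event_time", "duration",
          "time_remaining")]
}

#' Did the first mimicry event fall before the session midpoint?
#'
#' For each session with at least one mimicry event, flags whether the first
#' mimicry stimulus onset fell strictly before the halfway point of the
#' session duration (1 = before, 0 = after; an onset exactly at the midpoint
#' is conservatively coded 0). Sessions without mimicry get `NA`.
#'
#' @param events Validated event tibble.
#' @param records Stimulus records from [detect_rfm()].
#' @return Tibble: `session_id`, `first_rfm_time`, `midpoint`,
#'   `midpoint_flag`.
#' @export
midpoint_flag <- function(events, records) {
  st <- session_table(events)
  rfm <- records[records$replicated, ]
  first_rfm <- if (nrow(rfm) == 0) {
    tibble::tibble(session_id = character(), first_rfm_time = double())
  } else {
    dplyr::summarise(
      dplyr::group_by(rfm, .data$session_id),
      first_rfm_time = min(.data$onset), .groups = "drop"
    )
  }
  out <- dplyr::left_join(st[, c("session_id", "start", "duration")],
                          first_rfm, by = "session_id")
  out$midpoint <- out$start + out$duration / 2
  out$midpoint_flag <- ifelse(is.na(out$first_rfm_time), NA_integer_,
                              as.integer(out$first_rfm_time < out$midpoint))
  out[, c("session_id", "first_rfm_time", "midpoint", "midpoint_flag")]
}

#' Full per-session condition and duration summary
#'
#' Convenience wrapper joining [classify_condition()], [time_remaining()]
#' and [midpoint_flag()] into one per-session tibble.
#'
#' @param events Validated event tibble.
#' @param records Stimulus records from [detect_rfm()].
#' @param first_event Passed to [classify_condition()].
#' @return One row per session with condition, first event time, duration,
#'   time remaining and midpoint flag.
#' @export
session_conditions <- function(events, records,
                               first_event = c("first_rfm", "first_expression")) {
  cond <- classify_condition(events, records, first_event = first_event)
  tr <- time_remaining(events, cond)
  mf <- midpoint_flag(events, records)
  dplyr::left_join(tr, mf[, c("session_id", "first_rfm_time", "midpoint_flag")],
                   by = "session_id")
}
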