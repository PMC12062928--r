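#' Classify the perception condition of a stimulus
#'
#' A stimulus falling in the potential responder's frontal or lateral visual
#' field counts as perceived (`yes`); one falling in the blind area as not
#' perceived (`no`). Doubtful annotations stay `unknown` and are discarded
#' from downstream contingency/level analyses.
#'
#' @param perception Character vector of annotations (`frontal`, `lateral`,
#'   `blind`, `unknown`).
#' @return Character vector over `{"yes", "no", "unknown"}`.
#' @export
classify_perception <- function(perception) {
  out <- rep(NA_character_, length(perception))
  out[perception %in% c("frontal", "lateral")] <- "yes"
  out[perception == "blind"] <- "no"
  out[perception == "unknown"] <- "unknown"
  if (anyNA(out)) {
    abort_rows("perception annotation must be frontal/lateral/blind/unknown",
               which(is.na(out)))
  }
  out
}

#' Detect rapid facial mimicry in an event log
#'
#' Every facial expression is a potential stimulus toward the partner. A
#' stimulus counts as replicated when the partner emits an expression of the
#' same type (exact facial matching: PF answers PF, FPF answers FPF) with
#' onset strictly after the stimulus onset and at most `window_s` seconds
#' later. Latency is measured onset-to-onset. Pairing is greedy
#' earliest-first and a partner expression can answer at most one stimulus;
#' an expression consumed as a response is flagged (`is_response`) so that
#' sequential analyses do not treat it as its own focal event.
#'
#' @param events Validated event tibble from [load_sessions()] /
#'   [validate_sessions()].
#' @param window_s Response window in seconds (default 1.0).
#' @return Tibble of stimulus records: `session_id`, `stimulus_id`, `group`,
#'   `trigger`, `responder`, `expr_type`, `onset`, `perception`
#'   (`yes`/`no`/`unknown`), `replicated`, `latency`, `is_response`.
#' @export
detect_rfm <- function(events, window_s = 1.0) {
  if (!is_scalar_number(window_s) || window_s <= 0) abort("window_s must be > 0")
  expr <- events[events$event_kind == "expression", , drop = FALSE]
  if (nrow(expr) == 0) {
    return(tibble::tibble(
      session_id = character(), stimulus_id = character(), group = character(),
      trigger = character(), responder = character(), expr_type = character(),
      onset = double(), perception = character(), replicated = logical(),
      latency = double(), is_response = logical()
    ))
  }
  bad <- which(expr$player_a == expr$player_b)
  if (length(bad) > 0) abort("sessions need two distinct players")

  parts <- split(seq_len(nrow(expr)), expr$session_id)
  res <- lapply(parts, function(idx) {
    t0 <- expr$time_s[idx]
    actor <- expr$actor[idx]
    type <- expr$expr_type[idx]
    n <- length(idx)
    replicated <- logical(n)
    latency <- rep(NA_real_, n)
    consumed <- logical(n)
    # rows are already time-sorted within session (file order breaks ties)
    for (i in seq_len(n)) {
      cand <- which(!consumed & actor != actor[i] & type == type[i] &
                      t0 > t0[i] & t0 <= t0[i] + window_s)
      if (length(cand) > 0) {
        j <- cand[1]
        consumed[j] <- TRUE
        replicated[i] <- TRUE
        latency[i] <- t0[j] - t0[i]
      }
    }
    list(idx = idx, replicated = replicated, latency = latency, consumed = consumed)
  })
  idx <- unlist(lapply(res, `[[`, "idx"), use.names = FALSE)
  ord <- expr[idx, , drop = FALSE]
  tibble::tibble(
    session_id = ord$session_id,
    stimulus_id = paste0(ord$session_id, ":", stats::ave(
      seq_along(idx), ord$session_id, FUN = seq_along)),
    group = ord$group,
    trigger = ord$actor,
    responder = ifelse(ord$actor == ord$player_a, ord$player_b, ord$player_a),
    expr_type = ord$expr_type,
    onset = ord$time_s,
    perception = classify_perception(ord$perception),
    replicated = unlist(lapply(res, `[[`, "replicated"), use.names = FALSE),
    latency = unlist(lapply(res, `[[`, "latency"), use.names = FALSE),
    is_response = unlist(lapply(res, `[[`, "consumed"), use.names = FALSE)
  )
}

#' Perception-by-replication contingency table
#'
#' Cross-tabulates stimuli of one expression type by whether the potential
#' responder perceived them and whether they were replicated within the
#' mimicry window. Unknown-perception stimuli are discarded first.
#'
#' @param records Stimulus records from [detect_rfm()].
#' @param expr_type `"PF"` or `"FPF"`.
#' @param include_responses Count expressions that were themselves the
#'   response half of a mimicry pair as stimuli (default `FALSE`: only first
#'   stimuli enter the table, as in the perception analysis).
#' @return A 2x2 integer matrix (rows: perceived yes/no; columns: replicated
#'   yes/no) of class `contingency2x2`.
#' @export
build_contingency <- function(records, expr_type = c("PF", "FPF"),
                              include_responses = FALSE) {
  expr_type <- match.arg(expr_type)
  if (!include_responses) records <- records[!records$is_response, ]
  r <- records[records$expr_type == expr_type & records$perception != "unknown", ]
  tab <- matrix(
    c(sum(r$perception == "yes" & r$replicated),
      sum(r$perception == "yes" & !r$replicated),
      sum(r$perception == "no" & r$replicated),
      sum(r$perception == "no" & !r$replicated)),
    nrow = 2, byrow = TRUE,
    dimnames = list(perceived = c("yes", "no"), replicated = c("yes", "no"))
  )
  if (sum(tab) == 0) warn(paste0("no ", expr_type, " stimuli with known perception"))
  storage.mode(tab) <- "integer"
  class(tab) <- c("contingency2x2", class(tab))
  tab
}

#' Individual mimicry levels
#'
#' For each potential responder and expression type, the number of stimuli
#' they perceived, the number of those they replicated, and the mimicry
#' level replicated/perceived. Individuals who perceived no stimulus of a
#' type are excluded (the ratio is undefined).
#'
#' @param records Stimulus records from [detect_rfm()].
#' @return Tibble: `individual`, `expr_type`, `n_perceived`, `n_replicated`,
#'   `level`.
#' @export
rfm_level <- function(records) {
  r <- records[records$perception == "yes" & !records$is_response, ]
  out <- dplyr::summarise(
    dplyr::group_by(r, individual = .data$responder, .data$expr_type),
    n_perceived = dplyr::n(),
    n_replicated = sum(.data$replicated),
    level = .data$n_replicated / .data$n_perceived,
    .groups = "drop"
  )
  out[out$n_perceived >= 1, ]
}

#' Mixed-model design table for the mimicry analysis
#'
#' One row per stimulus with known perception: binary response (replicated
#' within the window), binary perception condition (1 = perceived), group
#' code (1 = BEA, 2 = VDS; other labels are coded by factor order), and the
#' trigger-responder dyad identifier intended as a random intercept. This
#' table is the exact input contract for an external binomial mixed-model
#' fit; [fit_rfm_glmm()] performs that fit and the full-vs-null
#' likelihood-ratio comparison (null = random factors only).
#'
#' @param records Stimulus records from [detect_rfm()], typically filtered
#'   to one expression type.
#' @return Tibble: `response`, `perception`, `group`, `dyad_id`.
#' @export
glmm_design_table <- function(records) {
  r <- records[records$perception != "unknown" & !records$is_response, ]
  grp <- r$group
  code <- if (all(grp %in% c("BEA", "VDS"))) {
    ifelse(grp == "BEA", 1L, 2L)
  } else {
    as.integer(factor(grp))
  }
  tibble::tibble(
    response = as.integer(r$replicated),
    perception = as.integer(r$perception == "yes"),
    group = code,
    dyad_id = paste(r$trigger, r$responder, sep = ":")
  )
}

#' Fit the binomial mimicry mixed model
#'
#' Fits `response ~ perception + group + (1 | dyad_id)` with a binomial
#' family via `lme4::glmer`, plus the null model with random factors only,
#' and compares them with a likelihood-ratio test. Estimation is delegated
#' entirely to `lme4`; this package only owns the design-table contract.
#' The group term is dropped automatically when only one group is present.
#'
#' @param design Design table from [glmm_design_table()].
#' @return List with `full`, `null` (fitted models), `coefficients`
#'   (tibble of fixed effects) and `lrt` (chisq, df, p_value).
#' @export
fit_rfm_glmm <- function(design) {
  if (!requireNamespace("lme4", quietly = TRUE)) {
    abort("fit_rfm_glmm() requires the lme4 package")
  }
  has_group <- length(unique(design$group)) > 1
  f_full <- if (has_group) {
    response ~ perception + group + (1 | dyad_id)
  } else {
    response ~ perception + (1 | dyad_id)
  }
  full <- lme4::glmer(f_full, data = design, family = stats::binomial())
  null <- lme4::glmer(response ~ 1 + (1 | dyad_id), data = design,
                      family = stats::binomial())
  lrt <- stats::anova(null, full)
  co <- summary(full)$coefficients
  list(
    full = full,
    null = null,
    coefficients = tibble::tibble(
      term = rownames(co), estimate = co[, 1], se = co[, 2],
      z = co[, 3], p_value = co[, 4]
    ),
    lrt = tibble::tibble(
      chisq = lrt$Chisq[2], df = lrt$Df[2], p_value = lrt$`Pr(>Chisq)`[2]
    )
  )
}
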