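#' Parameters for the synthetic play-session generator
#'
#' Returns the generator's parameter list. The defaults emulate the study
#' conditions the analysis assumes: dyadic sessions of categorized pattern
#' events at irregular (exponential) intervals averaging about 43 s of play,
#' play-face emissions at 0.8 per player per minute with 72% full play
#' faces, stimuli perceived with probability 0.7, congruent replication
#' within (0, 1] s at a higher rate when perceived (0.45 vs 0.12), the
#' per-pattern termination hazard multiplied by 0.4 after the first mimicry
#' event, a directed-offense bias of 0.3 toward the session initiator for
#' the four patterns after an unreplicated full play face, and a
#' pattern-diversity boost for the four patterns after an unreplicated play
#' face.
#'
#' @param n_dyads Number of dyads (default 10).
#' @param sessions_per_dyad Sessions generated per dyad (default 10).
#' @param mean_gap_s Mean inter-pattern gap in seconds (default 2.75).
#' @param category_weights Baseline offensive/defensive/neutral draw weights.
#' @param pattern_concentration Dirichlet concentration for the per-session
#'   pattern-type weights within each category; small values make sessions
#'   reuse a concentrated repertoire of favorite patterns, as real dyads do
#'   (default 0.15).
#' @param expression_rate_per_min Play-face emissions per player per minute
#'   (default 0.8).
#' @param fpf_fraction Probability an emission is a full play face
#'   (default 0.72).
#' @param p_perceived Probability the partner perceives a stimulus
#'   (default 0.7).
#' @param p_replicate_yes,p_replicate_no Replication probability given
#'   perceived / not perceived (defaults 0.45 / 0.12).
#' @param hazard_per_pattern Per-pattern session-termination probability
#'   (default 0.06).
#' @param hazard_multiplier_post_rfm Hazard multiplier applied after the
#'   first mimicry event (default 0.4; 1 = no effect).
#' @param offense_bias_post_fpf Probability that a pattern in the four-step
#'   window after an unreplicated FPF is forced to be an offensive act by
#'   the initiator (default 0.3; 0 = no effect).
#' @param diversity_boost_post_pf Draw patterns uniformly (maximum
#'   diversity) in the four-step window after an unreplicated PF
#'   (default TRUE).
#' @param expression_duration_range Uniform range of expression durations in
#'   seconds (default 0.5-4).
#' @param max_patterns Hard cap on patterns per session (default 400).
#' @return A named list of class `play_params`.
#' @export
play_params <- function(n_dyads = 10,
                        sessions_per_dyad = 10,
                        mean_gap_s = 2.75,
                        category_weights = c(offensive = 0.4, defensive = 0.2,
                                             neutral = 0.4),
                        pattern_concentration = 0.15,
                        expression_rate_per_min = 0.8,
                        fpf_fraction = 0.72,
                        p_perceived = 0.7,
                        p_replicate_yes = 0.45,
                        p_replicate_no = 0.12,
                        hazard_per_pattern = 0.06,
                        hazard_multiplier_post_rfm = 0.4,
                        offense_bias_post_fpf = 0.3,
                        diversity_boost_post_pf = TRUE,
                        expression_duration_range = c(0.5, 4),
                        max_patterns = 400) {
  p <- list(
    n_dyads = n_dyads, sessions_per_dyad = sessions_per_dyad,
    mean_gap_s = mean_gap_s, category_weights = category_weights,
    pattern_concentration = pattern_concentration,
    expression_rate_per_min = expression_rate_per_min,
    fpf_fraction = fpf_fraction, p_perceived = p_perceived,
    p_replicate_yes = p_replicate_yes, p_replicate_no = p_replicate_no,
    hazard_per_pattern = hazard_per_pattern,
    hazard_multiplier_post_rfm = hazard_multiplier_post_rfm,
    offense_bias_post_fpf = offense_bias_post_fpf,
    diversity_boost_post_pf = diversity_boost_post_pf,
    expression_duration_range = expression_duration_range,
    max_patterns = max_patterns
  )
  validate_play_params(p)
  class(p) <- c("play_params", "list")
  p
}

#' Generator parameters with every effect switched off
#'
#' Equal replication probabilities regardless of perception, termination
#' hazard unchanged by mimicry, no post-FPF offense bias and no post-PF
#' diversity boost: the null configuration used by type-I-error suites.
#'
#' @param ... Overrides passed on to [play_params()].
#' @return A `play_params` list.
#' @export
null_params <- function(...) {
  play_params(p_replicate_yes = 0.25, p_replicate_no = 0.25,
              hazard_multiplier_post_rfm = 1, offense_bias_post_fpf = 0,
              diversity_boost_post_pf = FALSE, ...)
}

validate_play_params <- function(p) {
  probs <- c(p$fpf_fraction, p$p_perceived, p$p_replicate_yes,
             p$p_replicate_no, p$offense_bias_post_fpf, p$hazard_per_pattern)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (p$hazard_per_pattern <= 0) abort("hazard_per_pattern must be > 0")
  if (p$hazard_multiplier_post_rfm <= 0) abort("hazard multiplier must be > 0")
  if (p$mean_gap_s <= 0) abort("mean_gap_s must be > 0")
  if (p$n_dyads < 1 || p$sessions_per_dyad < 1) abort("need at least one session")
  if (any(p$category_weights < 0) || sum(p$category_weights) <= 0) {
    abort("category weights must be non-negative and not all zero")
  }
  if (!all(c("offensive", "defensive", "neutral") %in% names(p$category_weights))) {
    abort("category_weights must name offensive, defensive and neutral")
  }
  invisible(p)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[] <- 1
  g / sum(g)
}

#' Generate a synthetic play-session event log with ground truth
#'
#' Builds sessions pattern by pattern under the generative model described
#' in [play_params()]: at each step an actor, a category (with the directed
#' offense bias active for four patterns after an unreplicated full play
#' face), a pattern (from per-session Dirichlet-weighted type distributions,
#' boosted to uniform for four patterns after an unreplicated play face) and
#' an exponential inter-event gap are drawn; play faces arise in the gaps at
#' the stated rate, are perceived with probability `p_perceived`, and are
#' congruently replicated within (0, 1] s with the perception-dependent
#' probability; the per-pattern termination hazard is multiplied by
#' `hazard_multiplier_post_rfm` after the first mimicry event. Identical
#' parameters and seed yield an identical log.
#'
#' @param params A [play_params()] list.
#' @param seed Integer seed.
#' @param ethogram Ethogram used for pattern draws and validation (default
#'   the packaged gorilla ethogram; the play-face entries themselves are
#'   never drawn as patterns).
#' @return A list of class `play_sim`: `events` (validated event tibble),
#'   `truth` (list with `sessions` and `stimuli` tibbles of the generating
#'   draws), `params`, `seed`.
#' @export
simulate_play <- function(params = play_params(), seed = 1,
                          ethogram = gorilla_ethogram()) {
  validate_play_params(params)
  set.seed(seed)
  eth <- ethogram[!ethogram$pattern %in% c("play face", "full play face"), ]
  cats <- c("offensive", "defensive", "neutral")
  pats_by_cat <- lapply(setNames(cats, cats), function(cc) eth$pattern[eth$category == cc])
  if (any(lengths(pats_by_cat) == 0)) abort("ethogram must cover all three categories")
  cw <- params$category_weights[cats] / sum(params$category_weights[cats])

  n_sessions <- params$n_dyads * params$sessions_per_dyad
  ids <- sprintf("G%02d", seq_len(2 * params$n_dyads))
  dur_lo <- params$expression_duration_range[1]
  dur_rng <- diff(params$expression_duration_range)
  p_expr_base <- params$expression_rate_per_min / 60

  ev_rows <- vector("list", n_sessions)
  truth_sessions <- vector("list", n_sessions)
  truth_stimuli <- vector("list", n_sessions)
  s <- 0L

  for (d in seq_len(params$n_dyads)) {
    pa <- ids[2 * d - 1]
    pb <- ids[2 * d]
    grp <- if (d <= ceiling(params$n_dyads / 2)) "VDS" else "BEA"
    dyad_id <- paste(pa, pb, sep = "-")
    for (k in seq_len(params$sessions_per_dyad)) {
      s <- s + 1L
      sid <- sprintf("S%04d", s)
      initiator <- if (runif(1) < 0.5) pa else pb
      partner_of <- function(x) if (x == pa) pb else pa
      w_by_cat <- lapply(pats_by_cat, function(pp)
        rdirichlet1(rep(params$pattern_concentration, length(pp))))

      cap <- params$max_patterns
      pt_time <- numeric(cap); pt_actor <- character(cap)
      pt_target <- character(cap); pt_name <- character(cap)
      ecap <- 64L
      ex_time <- numeric(ecap); ex_off <- numeric(ecap)
      ex_actor <- character(ecap); ex_type <- character(ecap)
      ex_perc <- character(ecap)
      ne <- 0L
      st_onset <- numeric(0); st_emitter <- character(0)
      st_type <- character(0); st_perc <- logical(0)
      st_repl <- logical(0); st_lat <- numeric(0)

      add_expr <- function(t0, actor, type, perc_annot) {
        ne <<- ne + 1L
        if (ne > length(ex_time)) {
          grow <- function(v) c(v, v[seq_along(v)])
          ex_time <<- grow(ex_time); ex_off <<- grow(ex_off)
          ex_actor <<- grow(ex_actor); ex_type <<- grow(ex_type)
          ex_perc <<- grow(ex_perc)
        }
        ex_time[ne] <<- t0
        ex_off[ne] <<- t0 + dur_lo + runif(1) * dur_rng
        ex_actor[ne] <<- actor
        ex_type[ne] <<- type
        ex_perc[ne] <<- perc_annot
      }

      hazard <- params$hazard_per_pattern
      had_rfm <- FALSE
      offense_window <- 0L
      diversity_window <- 0L
      t <- 0
      np <- 0L
      repeat {
        np <- np + 1L
        if (np == 1L) {
          actor <- initiator
          cat_i <- sample(cats, 1, prob = cw)
        } else if (offense_window > 0L && runif(1) < params$offense_bias_post_fpf) {
          actor <- initiator
          cat_i <- "offensive"
        } else {
          actor <- if (runif(1) < 0.5) pa else pb
          cat_i <- sample(cats, 1, prob = cw)
        }
        pool <- pats_by_cat[[cat_i]]
        pattern <- if (diversity_window > 0L && params$diversity_boost_post_pf) {
          pool[sample.int(length(pool), 1)]
        } else {
          pool[sample.int(length(pool), 1, prob = w_by_cat[[cat_i]])]
        }
        target <- if (cat_i == "neutral") NA_character_ else partner_of(actor)
        pt_time[np] <- t; pt_actor[np] <- actor
        pt_target[np] <- target; pt_name[np] <- pattern
        if (offense_window > 0L) offense_window <- offense_window - 1L
        if (diversity_window > 0L) diversity_window <- diversity_window - 1L

        if (np >= 2L && (runif(1) < hazard || np >= cap)) break

        gap <- rexp(1, rate = 1 / params$mean_gap_s)
        for (pl in c(pa, pb)) {
          if (runif(1) < min(1, p_expr_base * gap)) {
            onset <- t + runif(1) * gap
            type <- if (runif(1) < params$fpf_fraction) "FPF" else "PF"
            perceived <- runif(1) < params$p_perceived
            annot <- if (perceived) {
              if (runif(1) < 0.5) "frontal" else "lateral"
            } else "blind"
            add_expr(onset, pl, type, annot)
            p_rep <- if (perceived) params$p_replicate_yes else params$p_replicate_no
            replicated <- runif(1) < p_rep
            lat <- NA_real_
            if (replicated) {
              lat <- runif(1)  # uniform on (0, 1]
              resp_annot <- if (runif(1) < params$p_perceived) {
                if (runif(1) < 0.5) "frontal" else "lateral"
              } else "blind"
              add_expr(onset + lat, partner_of(pl), type, resp_annot)
              if (!had_rfm) {
                hazard <- hazard * params$hazard_multiplier_post_rfm
                had_rfm <- TRUE
              }
            } else if (type == "FPF") {
              offense_window <- 4L
            } else if (type == "PF") {
              diversity_window <- 4L
            }
            st_onset <- c(st_onset, onset); st_emitter <- c(st_emitter, pl)
            st_type <- c(st_type, type); st_perc <- c(st_perc, perceived)
            st_repl <- c(st_repl, replicated); st_lat <- c(st_lat, lat)
          }
        }
        t <- t + gap
      }

      # plain lists per session; a single tibble is assembled at the end
      n_all <- np + ne
      pi_ <- seq_len(np)
      ei <- seq_len(ne)
      ev_rows[[s]] <- list(
        session_id = rep(sid, n_all), group = rep(grp, n_all),
        player_a = rep(pa, n_all), player_b = rep(pb, n_all),
        event_kind = rep(c("pattern", "expression"), c(np, ne)),
        time_s = c(pt_time[pi_], ex_time[ei]),
        offset_s = c(rep(NA_real_, np), ex_off[ei]),
        actor = c(pt_actor[pi_], ex_actor[ei]),
        target = c(pt_target[pi_], rep(NA_character_, ne)),
        pattern = c(pt_name[pi_], rep(NA_character_, ne)),
        expr_type = c(rep(NA_character_, np), ex_type[ei]),
        perception = c(rep(NA_character_, np), ex_perc[ei])
      )
      truth_sessions[[s]] <- list(
        session_id = sid, dyad_id = dyad_id, group = grp, player_a = pa,
        player_b = pb, initiator = initiator, n_patterns = np,
        n_stimuli = length(st_onset), had_rfm = had_rfm
      )
      truth_stimuli[[s]] <- list(
        session_id = rep(sid, length(st_onset)), onset = st_onset,
        emitter = st_emitter, expr_type = st_type, perceived = st_perc,
        replicated = st_repl, latency = st_lat
      )
    }
  }

  bind_plain <- function(rows) {
    cols <- names(rows[[1]])
    tibble::as_tibble(lapply(setNames(cols, cols), function(cc)
      unlist(lapply(rows, `[[`, cc), use.names = FALSE)))
  }
  events <- validate_sessions(bind_plain(ev_rows), ethogram)
  structure(
    list(
      events = events,
      truth = list(sessions = bind_plain(truth_sessions),
                   stimuli = bind_plain(truth_stimuli)),
      params = params,
      seed = seed
    ),
    class = "play_sim"
  )
}
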