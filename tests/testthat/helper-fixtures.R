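# In-code fixture builders shared across the suite. All fixtures are
# generated programmatically; nothing binary ships with the tests.

test_eth <- gorilla_ethogram()

# one event-row spec
pat_ev <- function(t, actor, target = NA_character_, pattern = "play slap") {
  list(kind = "pattern", t = t, off = NA_real_, actor = actor,
       target = if (is.na(target)) NA_character_ else as.character(target),
       pattern = pattern, type = NA_character_, perc = NA_character_)
}

expr_ev <- function(t, actor, type = "PF", off = t + 1, perc = "frontal") {
  list(kind = "expression", t = t, off = off, actor = actor,
       target = NA_character_, pattern = NA_character_, type = type,
       perc = perc)
}

# assemble and validate a one-or-more-session log from event specs
make_log <- function(events, sid = "S1", players = c("A", "B"), group = "VDS",
                     ethogram = test_eth, validate = TRUE) {
  g <- function(f) vapply(events, function(e) e[[f]], events[[1]][[f]])
  raw <- tibble::tibble(
    session_id = if (length(sid) == 1) rep(sid, length(events)) else sid,
    group = group,
    player_a = players[1], player_b = players[2],
    event_kind = vapply(events, `[[`, "", "kind"),
    time_s = vapply(events, `[[`, 0, "t"),
    offset_s = vapply(events, `[[`, 0, "off"),
    actor = vapply(events, `[[`, "", "actor"),
    target = vapply(events, `[[`, "", "target"),
    pattern = vapply(events, `[[`, "", "pattern"),
    expr_type = vapply(events, `[[`, "", "type"),
    perception = vapply(events, `[[`, "", "perc")
  )
  if (validate) validate_sessions(raw, ethogram) else raw
}

# log engineered to produce the given (perceived&replicated, perceived&not,
# not-perceived&replicated, not-perceived&not) contingency counts per type:
# one two-player session per stimulus, response 0.5 s after the stimulus
contingency_log <- function(counts_by_type) {
  rows <- list()
  s <- 0
  for (tt in names(counts_by_type)) {
    cc <- counts_by_type[[tt]]
    specs <- data.frame(
      perc = rep(c("frontal", "frontal", "blind", "blind"), cc),
      repl = rep(c(TRUE, FALSE, TRUE, FALSE), cc)
    )
    for (i in seq_len(nrow(specs))) {
      s <- s + 1
      sid <- sprintf("C%04d", s)
      ev <- list(expr_ev(5, "A", type = tt, perc = specs$perc[i]))
      if (specs$repl[i]) ev <- c(ev, list(expr_ev(5.5, "B", type = tt)))
      rows[[s]] <- make_log(ev, sid = sid, validate = FALSE)
    }
  }
  validate_sessions(dplyr::bind_rows(rows), test_eth)
}

# synthetic FACS-style binary AU configurations emulating the qualitative
# structure reported for the two expression types: the shared mouth-opening
# units in (almost) every configuration, the upper-lip raiser and mouth
# stretch essentially confined to the full play face
facs_configs_synthetic <- function() {
  core <- c("AU12", "AU16", "AU25", "AU26")
  pf <- lapply(1:8, function(i) {
    aus <- core
    if (i <= 2) aus <- c(aus, "AU10")  # rare in PF
    if (i == 1) aus <- c(aus, "AU27")  # rare in PF
    if (i %% 2 == 0) aus <- c(aus, "AU1")
    aus
  })
  fpf <- lapply(1:9, function(i) {
    aus <- c(core, "AU06", "AU09", "AU10", "AU27")
    if (i %% 3 == 0) aus <- c(aus, "AU17")
    aus
  })
  tibble::tibble(
    subject = c(sprintf("pf%02d", 1:8), sprintf("fpf%02d", 1:9)),
    expression = rep(c("PF", "FPF"), c(8, 9)),
    aus = c(vapply(pf, paste, "", collapse = ","),
            vapply(fpf, paste, "", collapse = ","))
  )
}

# write a small OpenFace-style per-frame CSV (whitespace-padded headers, as
# the real tool emits) and return its path
write_openface_fixture <- function(dir, au10 = c(0.2, 1.4, 0.9),
                                   name = "clip1.csv") {
  path <- file.path(dir, name)
  n <- length(au10)
  header <- "frame, timestamp, confidence, AU06_r, AU10_r, AU12_r"
  body <- sprintf("%d, %.2f, 0.98, %.2f, %.2f, %.2f",
                  seq_len(n), seq_len(n) / 30, seq(0.1, 0.5, length.out = n),
                  au10, rev(au10))
  writeLines(c(header, body), path)
  path
}

# per-clip AU intensity records for n_subj subjects with both expressions;
# shift adds the given intensity to AU10 under FPF
intensity_records <- function(n_subj, shift_au10 = 0, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_subj)) {
    for (tt in c("PF", "FPF")) {
      base <- stats::runif(3, 0.2, 1.5)
      au10 <- stats::runif(1, 0.2, 1.0) + if (tt == "FPF") shift_au10 else 0
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject = sprintf("g%02d", s), expression = tt,
        clip = paste0(s, tt), n_frames = 10L,
        AU06 = base[1], AU10 = au10, AU12 = base[2], AU25 = base[3]
      )
    }
  }
  dplyr::bind_rows(rows)
}
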