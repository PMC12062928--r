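rand_window <- function(n, players = c("A", "B")) {
  actor <- sample(players, n, replace = TRUE)
  category <- sample(ETHOGRAM_CATEGORIES, n, replace = TRUE)
  target <- ifelse(category == "neutral" & stats::runif(n) < 0.5,
                   NA_character_,
                   ifelse(actor == players[1], players[2], players[1]))
  tibble::tibble(
    actor = actor, target = target, category = category,
    pattern = sample(c("play slap", "play bite", "play flee", "pirouetting",
                       "tickle", "somersault"), n, replace = TRUE)
  )
}

# independent count-based oracle for the asymmetry index
pai_oracle <- function(w, a, b) {
  dir_count <- function(cat, from, to) {
    sum(w$category == cat & w$actor == from & !is.na(w$target) & w$target == to)
  }
  (dir_count("offensive", a, b) + dir_count("defensive", b, a) -
     dir_count("offensive", b, a) - dir_count("defensive", a, b)) / nrow(w)
}

test_that("the asymmetry index matches its hand-evaluated definition", {
  w <- tibble::tibble(
    actor = c("A", "A", "B", "A"),
    target = c("B", "B", "A", NA),
    category = c("offensive", "offensive", "defensive", "neutral"),
    pattern = c("play bite", "play slap", "play flee", "pirouetting")
  )
  expect_equal(pai(w, "A", "B"), 0.75)  # (2 + 1 - 0) / 4
  expect_equal(pai(w, "B", "A"), -0.75)

  all_neutral <- tibble::tibble(actor = "A", target = NA_character_,
                                category = rep("neutral", 3),
                                pattern = rep("somersault", 3))
  expect_equal(pai(all_neutral, "A", "B"), 0)
  expect_true(is.na(pai(w[0, ], "A", "B")))
})

test_that("asymmetry and diversity obey their bounds and symmetries", {
  set.seed(41)
  for (i in 1:1000) {
    w <- rand_window(sample(1:8, 1))
    v <- pai(w, "A", "B")
    expect_gte(v, -1); expect_lte(v, 1)
    expect_equal(pai(w, "B", "A"), -v)            # antisymmetry
    expect_equal(v, pai_oracle(w, "A", "B"))      # brute-force agreement
    h <- shannon_index(w)
    expect_gte(h, 0)
    expect_lte(h, log(length(unique(w$pattern))) + 1e-12)
  }
})

test_that("the diversity index reproduces the worked five-pattern session", {
  session <- c("play slapping", "play slapping", "play sheltering",
               "play slapping", "pirouetting")
  expect_equal(shannon_index(session), 0.9502705, tolerance = 1e-6)
  expect_equal(shannon_index(rep("play slap", 7)), 0)
  expect_equal(shannon_index(c("a", "b", "c", "d")), log(4))
})

test_that("focal events keep stimuli but drop the response half of a pair", {
  log <- make_log(list(
    pat_ev(0, "A", "B"), expr_ev(5, "A", "PF"), expr_ev(5.5, "B", "PF"),
    expr_ev(20, "B", "FPF")
  ))
  fo <- focal_events(detect_rfm(log))
  expect_equal(nrow(fo), 2)
  expect_setequal(fo$kind, c("PF_RFM", "FPF_not_mim"))
  expect_equal(fo$onset[fo$kind == "PF_RFM"], 5)
})

test_that("window extraction honors the spacing and empty-side rules", {
  # 10 patterns at t = 1..10, focal expression at 5.5: full 4+4 windows
  pats <- lapply(1:10, function(i) pat_ev(i, ifelse(i %% 2, "A", "B"),
                                          ifelse(i %% 2, "B", "A"), "play slap"))
  log <- make_log(c(pats, list(expr_ev(5.5, "A", "PF", perc = "blind"))))
  fo <- focal_events(detect_rfm(log))
  w <- extract_windows(log, fo)
  expect_equal(nrow(w), 1)
  expect_equal(w$n_before, 4)
  expect_equal(w$n_after, 4)
  expect_equal(w$before[[1]]$time_s, 2:5)
  expect_equal(w$after[[1]]$time_s, 6:9)

  # two focal events with only 5 intervening patterns: the later is excluded
  pats <- lapply(1:20, function(i) pat_ev(i, "A", "B", "play slap"))
  log <- make_log(c(pats, list(expr_ev(6.5, "A", "PF", perc = "blind"),
                               expr_ev(12.5, "A", "PF", perc = "blind"))))
  fo <- focal_events(detect_rfm(log))
  w <- extract_windows(log, fo)
  expect_equal(nrow(w), 1)
  expect_equal(w$onset, 6.5)

  # with >= 12 intervening patterns both are retained
  log <- make_log(c(pats, list(expr_ev(3.5, "A", "PF", perc = "blind"),
                               expr_ev(16.5, "A", "PF", perc = "blind"))))
  fo <- focal_events(detect_rfm(log))
  expect_equal(nrow(extract_windows(log, fo)), 2)

  # focal at session start (no patterns before) is dropped;
  # short but non-empty sides are kept
  log <- make_log(list(expr_ev(0.5, "A", "PF", perc = "blind"),
                       pat_ev(1, "A", "B"), pat_ev(2, "B", "A"),
                       expr_ev(2.5, "A", "PF", perc = "blind"),
                       pat_ev(3, "A", "B")))
  fo <- focal_events(detect_rfm(log))
  w <- extract_windows(log, fo)
  expect_equal(nrow(w), 1)
  expect_equal(w$onset, 2.5)
  expect_equal(w$n_before, 2)
  expect_equal(w$n_after, 1)
})

test_that("before/after indices delegate and respect symmetric windows", {
  pats <- c(
    lapply(1:4, function(i) pat_ev(i, "A", "B", "play bite")),
    lapply(6:9, function(i) pat_ev(i, "A", "B", "play bite"))
  )
  log <- make_log(c(pats, list(expr_ev(5, "A", "PF", perc = "blind"))))
  fo <- focal_events(detect_rfm(log))
  idx <- before_after_indices(extract_windows(log, fo))
  expect_equal(idx$pai_before, idx$pai_after)
  expect_equal(idx$h_before, idx$h_after)
  expect_equal(idx$pai_before, 1)  # all offense by one player
  expect_equal(idx$h_before, 0)
})

test_that("injected sequential effects are recovered from generated data", {
  sim <- simulate_play(play_params(n_dyads = 10, sessions_per_dyad = 30),
                       seed = 14)
  rec <- detect_rfm(sim$events)
  idx <- before_after_indices(extract_windows(sim$events, focal_events(rec)))
  fpf <- idx[idx$kind == "FPF_not_mim", ]
  pfn <- idx[idx$kind == "PF_not_mim", ]
  expect_gt(nrow(fpf), 100)
  expect_gt(mean(fpf$pai_after - fpf$pai_before), 0)   # offense bias
  expect_gt(mean(pfn$h_after - pfn$h_before), 0)       # diversity boost
  # the asymmetry shift does not leak into the diversity channel
  expect_lt(abs(mean(fpf$h_after - fpf$h_before)), 0.15)
})
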