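# End-to-end runners tying the stages into the four analyses. Each takes a
# validated event log, returns tibble-valued results, and can mirror them to
# TSV files (plus a manifest capturing config, seed and package version) so a
# run is reproducible bit for bit.

write_stage_outputs <- function(out_dir, outputs, config) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(outputs)) {
    readr::write_tsv(outputs[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                     progress = FALSE)
  }
  manifest <- tibble::tibble(
    key = c("package", "version", names(config)),
    value = c("playmimicry",
              as.character(utils::packageVersion("playmimicry")),
              vapply(config, function(x) paste(format(x), collapse = ","),
                     character(1)))
  )
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"), progress = FALSE)
  invisible(out_dir)
}

#' Run the rapid-facial-mimicry analysis
#'
#' Detects mimicry, builds the perception-by-replication contingency table
#' and Yates chi-square test per expression type, the per-individual
#' mimicry levels, and the mixed-model design table.
#'
#' @param events Validated event tibble.
#' @param window_s Mimicry window in seconds (default 1.0).
#' @param out_dir Optional directory for TSV outputs and a manifest.
#' @return List: `records`, `contingency` (named list of 2x2 tables),
#'   `tests` (chi-square results), `levels`, `design`.
#' @export
run_rfm <- function(events, window_s = 1.0, out_dir = NULL) {
  records <- detect_rfm(events, window_s = window_s)
  types <- intersect(c("PF", "FPF"), unique(records$expr_type))
  contingency <- lapply(setNames(types, types),
                        function(tt) build_contingency(records, tt))
  tests <- dplyr::bind_rows(lapply(types, function(tt) {
    res <- yates_chi2(contingency[[tt]])
    res$note <- tt
    res
  }))
  design <- glmm_design_table(records)
  levels <- rfm_level(records)
  contingency_tbl <- dplyr::bind_rows(lapply(types, function(tt) {
    m <- contingency[[tt]]
    tibble::tibble(expr_type = tt,
                   perceived_replicated = m[1, 1],
                   perceived_not = m[1, 2],
                   not_perceived_replicated = m[2, 1],
                   not_perceived_not = m[2, 2])
  }))
  write_stage_outputs(out_dir,
                      list(rfm_records = records, rfm_contingency = contingency_tbl,
                           rfm_tests = tidy(tests), rfm_levels = levels,
                           glmm_design = design),
                      list(stage = "rfm", window_s = window_s))
  list(records = records, contingency = contingency, tests = tests,
       levels = levels, design = design)
}

#' Run the sequential before/after index analysis
#'
#' Cuts four-pattern windows around every retained focal event (unreplicated
#' expressions and mimicry events), computes the asymmetry and diversity
#' indices on each side, and tests the before-vs-after contrast per focal
#' kind with the exact Wilcoxon signed-rank test.
#'
#' @param events Validated event tibble.
#' @param k Window size in patterns (default 4).
#' @param min_separation Spacing requirement between consecutive focal
#'   events (default 4).
#' @param window_s Mimicry window in seconds (default 1.0).
#' @param orientation Asymmetry orientation, see [before_after_indices()].
#' @param out_dir Optional output directory.
#' @return List: `indices` (per focal event) and `tests` (one Wilcoxon row
#'   per focal kind and index).
#' @export
run_sequential <- function(events, k = 4, min_separation = 4, window_s = 1.0,
                           orientation = "initiator", out_dir = NULL) {
  records <- detect_rfm(events, window_s = window_s)
  focal <- focal_events(records)
  windows <- extract_windows(events, focal, k = k, min_separation = min_separation)
  idx <- before_after_indices(windows, orientation = orientation)
  tests <- dplyr::bind_rows(lapply(sort(unique(idx$kind)), function(kk) {
    sub <- idx[idx$kind == kk, ]
    if (nrow(sub) < 2) return(NULL)
    pai_t <- wilcoxon_exact(sub$pai_before, sub$pai_after)
    h_t <- wilcoxon_exact(sub$h_before, sub$h_after)
    pai_t$note <- paste0(kk, ": PAI before vs after")
    h_t$note <- paste0(kk, ": H' before vs after")
    dplyr::bind_rows(pai_t, h_t)
  }))
  write_stage_outputs(out_dir,
                      list(sequential_indices = idx,
                           sequential_tests = tidy(tests)),
                      list(stage = "sequential", k = k,
                           min_separation = min_separation,
                           window_s = window_s, orientation = orientation))
  list(indices = idx, tests = tests)
}

#' Run the session-duration analysis
#'
#' Classifies every session into the five mimicry conditions, computes the
#' time remaining from the first qualifying event to session end, compares
#' it across conditions with the Monte-Carlo Kruskal-Wallis test and Dunn
#' post hocs, and tests with an exact binomial whether first mimicry events
#' fall before the session midpoint.
#'
#' @param events Validated event tibble.
#' @param window_s Mimicry window in seconds (default 1.0).
#' @param n_perm Kruskal-Wallis permutations (default 10000).
#' @param seed Seed for the permutation stream.
#' @param out_dir Optional output directory.
#' @return List: `conditions` (per session), `kw`, `posthoc`, `midpoint`
#'   (binomial test row).
#' @export
run_durations <- function(events, window_s = 1.0, n_perm = 10000, seed = NULL,
                          out_dir = NULL) {
  records <- detect_rfm(events, window_s = window_s)
  conditions <- session_conditions(events, records)
  used <- conditions[conditions$condition != "excluded" &
                       !is.na(conditions$time_remaining), ]
  kw <- if (length(unique(used$condition)) >= 2) {
    kruskal_wallis_mc(used$time_remaining, used$condition,
                      n_perm = n_perm, seed = seed)
  } else {
    NULL
  }
  posthoc <- if (length(unique(used$condition)) >= 2) {
    dunn_bonferroni(used$time_remaining, used$condition)
  } else {
    NULL
  }
  flags <- conditions$midpoint_flag[!is.na(conditions$midpoint_flag)]
  midpoint <- if (length(flags) > 0) {
    binomial_exact(sum(flags == 1L), length(flags))
  } else {
    NULL
  }
  outputs <- list(duration_conditions = conditions)
  if (!is.null(kw)) outputs$duration_kw <- tidy(kw)
  if (!is.null(posthoc)) outputs$duration_posthoc <- posthoc
  if (!is.null(midpoint)) outputs$duration_midpoint <- tidy(midpoint)
  write_stage_outputs(out_dir, outputs,
                      list(stage = "durations", window_s = window_s,
                           n_perm = n_perm, seed = seed %||% NA))
  list(conditions = conditions, kw = kw, posthoc = posthoc, midpoint = midpoint)
}

#' Run the per-individual play-face rate analysis
#'
#' Computes per-individual PF and FPF rates per session and compares them
#' with a paired t-test.
#'
#' @param summaries Per-individual summary tibble (e.g.
#'   [group_composition()]).
#' @param zero_convention See [rates_per_session()].
#' @param out_dir Optional output directory.
#' @return List: `rates` (summaries with rate columns), `means` (one-row
#'   tibble of means and SEs), `test` (paired t row).
#' @export
run_rates <- function(summaries, zero_convention = "zero", out_dir = NULL) {
  rates <- rates_per_session(summaries, zero_convention)
  n <- nrow(rates)
  means <- tibble::tibble(
    n = n,
    pf_mean = mean(rates$pf_rate),
    pf_se = sd(rates$pf_rate) / sqrt(n),
    fpf_mean = mean(rates$fpf_rate),
    fpf_se = sd(rates$fpf_rate) / sqrt(n)
  )
  test <- paired_t(rates$pf_rate, rates$fpf_rate)
  write_stage_outputs(out_dir,
                      list(rates = rates, rate_means = means,
                           rate_test = tidy(test)),
                      list(stage = "rates", zero_convention = zero_convention))
  list(rates = rates, means = means, test = test)
}
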