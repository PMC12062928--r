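# The 17 AUs whose intensity (0-5) the automated face coder estimates; AU16
# and AU27 have no intensity estimate and only appear in binary FACS codings.
OPENFACE_INTENSITY_AUS <- paste0("AU", sprintf("%02d", c(
  1, 2, 4, 5, 6, 7, 9, 10, 12, 14, 15, 17, 20, 23, 25, 26, 45)))

#' Read an OpenFace-style AU-intensity table
#'
#' Reads one comma-separated per-frame output file (headers may be
#' whitespace-padded, as the standard tool writes them), keeps the AU
#' intensity columns (suffix `_r`) and reduces the frames to a single
#' per-clip record with a configurable aggregator; the default takes the
#' maximum intensity per AU across frames, i.e. the expression's apex.
#'
#' @param path Path to the CSV file (one clip).
#' @param aggregate `"max"` (default), `"mean"` or `"median"`.
#' @param subject,expression,clip Optional identifiers stored with the
#'   record; `clip` defaults to the file name.
#' @return A one-row tibble: `subject`, `expression`, `clip`, `n_frames`,
#'   then one column per AU (`AU01`, `AU02`, ...).
#' @export
read_openface_csv <- function(path, aggregate = c("max", "mean", "median"),
                              subject = NA_character_, expression = NA_character_,
                              clip = NULL) {
  aggregate <- match.arg(aggregate)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  names(raw) <- trimws(names(raw))
  if (nrow(raw) == 0) abort(paste0("no frames in ", path))
  au_cols <- grep("^AU[0-9]+_r$", names(raw), value = TRUE)
  if (length(au_cols) == 0) abort(paste0("no AU intensity (_r) columns in ", path))
  agg_fun <- switch(aggregate, max = max, mean = mean, median = median)
  vals <- vapply(raw[au_cols], function(v) agg_fun(as.numeric(v)), numeric(1))
  names(vals) <- sub("_r$", "", names(vals))
  out <- tibble::tibble(
    subject = subject, expression = expression,
    clip = clip %||% basename(path), n_frames = nrow(raw)
  )
  dplyr::bind_cols(out, tibble::as_tibble(as.list(vals)))
}

# normalise configs$aus (comma-joined string or list column) to a list of
# upper-case AU code vectors
au_sets <- function(aus) {
  if (is.list(aus)) {
    lapply(aus, function(x) toupper(trimws(x)))
  } else {
    lapply(strsplit(as.character(aus), ","), function(x) toupper(trimws(x)))
  }
}

#' Action units always or almost always present in an expression
#'
#' From binary FACS-style configurations (one row per coded expression
#' instance, each listing its active AUs), returns the AUs whose presence
#' frequency reaches `threshold` for the requested expression type, sorted
#' by decreasing frequency. With `threshold = 1` this is exactly the
#' intersection of all configurations.
#'
#' @param configs Tibble with columns `subject`, `expression` and `aus`
#'   (comma-joined AU codes or a list-column of character vectors).
#' @param expression Expression type to summarise (`"PF"` or `"FPF"`).
#' @param threshold Minimum presence frequency (default 0.8).
#' @return Tibble: `au`, `n_present`, `n_configs`, `frequency`.
#' @export
configuration_summary <- function(configs, expression, threshold = 0.8) {
  cc <- configs[configs$expression == expression, ]
  if (nrow(cc) == 0) abort(paste0("no configurations for ", expression))
  sets <- au_sets(cc$aus)
  all_aus <- sort(unique(unlist(sets)))
  n <- length(sets)
  counts <- vapply(all_aus, function(a) sum(vapply(sets, function(s) a %in% s,
                                                   logical(1))), numeric(1))
  out <- tibble::tibble(au = all_aus, n_present = as.integer(unname(counts)),
                        n_configs = n, frequency = unname(counts) / n)
  out <- out[out$frequency >= threshold, ]
  out[order(-out$frequency, out$au), ]
}

#' Compare AU intensities between the two play-face types
#'
#' Per-individual comparison of AU intensities between PF and FPF: each
#' subject's clips are reduced to a per-expression median intensity per AU,
#' then each AU is tested across subjects with an exact Wilcoxon signed-rank
#' test. The Bonferroni threshold is `alpha_family / number of AUs tested`;
#' the result flags AUs below it and marks the minimum-p AU.
#'
#' @param records Per-clip intensity records (rows as produced by
#'   [read_openface_csv()], with `subject` and `expression` filled in).
#' @param alpha_family Family-wise alpha (default 0.05).
#' @return Tibble with one row per AU: `au`, `n_subjects`, `T`, `ties`,
#'   `p_value`, `direction`, `threshold`, `flagged`, `is_min_p`.
#' @export
compare_intensities <- function(records, alpha_family = 0.05) {
  au_cols <- grep("^AU[0-9]+$", names(records), value = TRUE)
  if (length(au_cols) == 0) abort("no AU columns in records")
  long <- tidyr::pivot_longer(records[, c("subject", "expression", au_cols)],
                              dplyr::all_of(au_cols),
                              names_to = "au", values_to = "intensity")
  med <- dplyr::summarise(
    dplyr::group_by(long, .data$subject, .data$expression, .data$au),
    intensity = median(.data$intensity), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(med, names_from = "expression",
                             values_from = "intensity")
  if (!all(c("PF", "FPF") %in% names(wide))) {
    abort("records must contain both PF and FPF expressions")
  }
  wide <- wide[!is.na(wide$PF) & !is.na(wide$FPF), ]
  n_subj <- length(unique(wide$subject))
  if (n_subj < 2) abort("need at least two subjects with both expressions")
  threshold <- alpha_family / length(au_cols)
  rows <- lapply(sort(au_cols), function(a) {
    w <- wide[wide$au == a, ]
    res <- wilcoxon_exact(w$PF, w$FPF)
    diff_med <- median(w$FPF - w$PF)
    tibble::tibble(
      au = a, n_subjects = nrow(w), T = res$value, ties = res$ties,
      p_value = res$p_value,
      direction = if (is.na(res$p_value) || diff_med == 0) "none"
                  else if (diff_med > 0) "FPF>PF" else "PF>FPF"
    )
  })
  out <- dplyr::bind_rows(rows)
  out$threshold <- threshold
  out$flagged <- !is.na(out$p_value) & out$p_value <= threshold
  finite_p <- ifelse(is.na(out$p_value), Inf, out$p_value)
  out$is_min_p <- finite_p == min(finite_p) & is.finite(min(finite_p))
  out
}
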