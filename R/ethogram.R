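#' Load an ethogram table
#'
#' Reads a tab-separated ethogram mapping each behavioral pattern to one of
#' the three play categories (`offensive`, `defensive`, `neutral`). Pattern
#' names are matched case-insensitively after trimming whitespace and must be
#' unique; any other category value is rejected with the offending row.
#'
#' @param path Path to a TSV file with columns `pattern` and `category`.
#' @return A tibble with columns `pattern` (normalised to lower case) and
#'   `category`, one row per pattern.
#' @export
#' @examples
#' eth <- gorilla_ethogram()
#' dplyr::count(eth, category)
load_ethogram <- function(path) {
  if (!file.exists(path)) abort(paste0("ethogram file not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) abort("ethogram file is empty")
  missing_cols <- setdiff(c("pattern", "category"), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("ethogram is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  eth <- tibble::tibble(
    pattern = norm_pattern(raw$pattern),
    category = norm_pattern(raw$category)
  )
  bad_cat <- which(!eth$category %in% ETHOGRAM_CATEGORIES)
  if (length(bad_cat) > 0) {
    abort_rows(paste0("unknown category '", eth$category[bad_cat[1]],
                      "' for pattern '", eth$pattern[bad_cat[1]], "'"), bad_cat)
  }
  dup <- which(duplicated(eth$pattern))
  if (length(dup) > 0) {
    abort_rows(paste0("duplicated pattern '", eth$pattern[dup[1]], "'"), dup)
  }
  if (any(eth$pattern == "")) abort("empty pattern name in ethogram")
  eth
}

#' Packaged lowland-gorilla play ethogram
#'
#' The ethogram of lowland-gorilla play and play-adjacent behavioral
#' patterns shipped with the package (41 entries). Directed play jumps are
#' offensive while the solitary form (`play jump solo`) is neutral; play
#' faces themselves are carried as neutral patterns so that full event logs
#' validate against a single catalog.
#'
#' @return A tibble with columns `pattern` and `category`.
#' @export
gorilla_ethogram <- function() {
  load_ethogram(system.file("extdata", "gorilla_ethogram.tsv",
                            package = "playmimicry", mustWork = TRUE))
}

#' Look up pattern categories
#'
#' @param ethogram An ethogram tibble from [load_ethogram()].
#' @param patterns Character vector of pattern names (matched
#'   case-insensitively after trimming).
#' @return Character vector of categories; unknown patterns raise an error.
#' @export
pattern_category <- function(ethogram, patterns) {
  key <- norm_pattern(patterns)
  idx <- match(key, ethogram$pattern)
  if (anyNA(idx)) {
    abort_rows(paste0("pattern(s) not in ethogram: ",
                      paste(unique(key[is.na(idx)]), collapse = ", ")),
               which(is.na(idx)))
  }
  ethogram$category[idx]
}
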