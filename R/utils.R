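# internal helpers shared across modules

#' Canonical behavioral categories
#'
#' The three categories every ethogram entry must carry: offensive (attack
#' directed at the partner), defensive (avoidance/protection), neutral
#' (neither).
#'
#' @export
ETHOGRAM_CATEGORIES <- c("offensive", "defensive", "neutral")

# case/whitespace-normalised pattern key
norm_pattern <- function(x) tolower(trimws(x))

# stop with row context
abort_rows <- function(msg, rows) {
  rows <- utils::head(rows, 10)
  abort(paste0(msg, " (row", if (length(rows) > 1) "s", " ",
               paste(rows, collapse = ", "), ")"))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# test-result row shared by the stats module; a one-row tibble subclass so
# broom-style tidy()/glance() and bind_rows() both work
new_ethotest <- function(method, statistic, value, df = NA_real_, n = NA_integer_,
                         ties = NA_integer_, p_value = NA_real_,
                         n_perm = NA_integer_, seed = NA_integer_,
                         correction = NA_character_, note = NA_character_) {
  out <- tibble::tibble(
    method = method, statistic = statistic, value = value, df = df,
    n = as.integer(n), ties = as.integer(ties), p_value = p_value,
    n_perm = as.integer(n_perm), seed = as.integer(seed),
    correction = correction, note = note
  )
  class(out) <- c("ethotest", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.ethotest <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ethotest")
  out
}

#' @exportS3Method generics::glance
glance.ethotest <- function(x, ...) {
  tidy(x)[, c("method", "value", "p_value")]
}
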