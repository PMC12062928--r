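# ggplot2 views of the main result types

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a perception-by-replication contingency table
#'
#' @param tab A `contingency2x2` matrix from [build_contingency()].
#' @param ... Unused.
#' @return A ggplot object (grouped bar chart of the four cells).
#' @exportS3Method ggplot2::autoplot
autoplot.contingency2x2 <- function(tab, ...) {
  df <- tibble::tibble(
    perceived = rep(c("perceived", "not perceived"), each = 2),
    replicated = rep(c("replicated", "not replicated"), 2),
    n = as.vector(t(unclass(tab)))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$perceived, y = .data$n,
                                   fill = .data$replicated)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "stimuli", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot before/after index contrasts per focal kind
#'
#' Paired-point view of the asymmetry (PAI) or diversity (H') index before
#' and after each focal event, faceted by focal kind.
#'
#' @param indices Output of [before_after_indices()].
#' @param index `"pai"` or `"h"`.
#' @return A ggplot object.
#' @export
plot_before_after <- function(indices, index = c("pai", "h")) {
  index <- match.arg(index)
  cols <- paste0(index, c("_before", "_after"))
  long <- tidyr::pivot_longer(indices[, c("focal_id", "kind", cols)],
                              dplyr::all_of(cols),
                              names_to = "side", values_to = "value")
  long$side <- factor(sub(paste0(index, "_"), "", long$side),
                      levels = c("before", "after"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$side, y = .data$value,
                                     group = .data$focal_id)) +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::facet_wrap(~kind) +
    ggplot2::labs(x = NULL, y = if (index == "pai") "PAI" else "H'") +
    ggplot2::theme_minimal()
}

#' Plot time remaining by session condition
#'
#' Box-and-point view of the seconds between the first qualifying event and
#' session end across the five session conditions.
#'
#' @param conditions Output of [session_conditions()] / [time_remaining()].
#' @return A ggplot object.
#' @export
plot_time_remaining <- function(conditions) {
  used <- conditions[conditions$condition != "excluded" &
                       !is.na(conditions$time_remaining), ]
  ggplot2::ggplot(used, ggplot2::aes(x = .data$condition,
                                     y = .data$time_remaining)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4) +
    ggplot2::labs(x = NULL, y = "time remaining (s)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot per-individual play-face rates
#'
#' Paired per-individual PF and FPF rates per session.
#'
#' @param rates Output of [rates_per_session()] (needs a `subject` column).
#' @return A ggplot object.
#' @export
plot_rates <- function(rates) {
  long <- tidyr::pivot_longer(rates[, c("subject", "pf_rate", "fpf_rate")],
                              c("pf_rate", "fpf_rate"),
                              names_to = "type", values_to = "rate")
  long$type <- factor(ifelse(long$type == "pf_rate", "PF", "FPF"),
                      levels = c("PF", "FPF"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$type, y = .data$rate,
                                     group = .data$subject)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "expressions per session") +
    ggplot2::theme_minimal()
}
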