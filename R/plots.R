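#' Box plot of retention fold changes by intron group
#'
#' Mirrors the standard presentation of the group analysis: one box per
#' architecture group (per knockdown), fold changes on a log2 axis, the
#' all-intron background as the first box.
#'
#' @param folds Tibble `intron_id`, `fold`, optional `knockdown`.
#' @param membership Long membership tibble ([group_membership()]) or a
#'   classified intron table.
#' @return A ggplot object.
#' @export
plot_group_folds <- function(folds, membership) {
  if (!"knockdown" %in% names(folds)) folds$knockdown <- "knockdown"
  if (!"group" %in% names(membership)) membership <- group_membership(membership)
  df <- bind_rows(
    folds |> mutate(group = "all introns"),
    membership |> inner_join(folds, by = "intron_id"))
  df$group <- factor(df$group,
                     levels = c("all introns", intron_group_labels()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$fold)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, fill = "grey85") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::facet_wrap(ggplot2::vars(.data$knockdown)) +
    ggplot2::labs(x = NULL, y = "retention fold change (knockdown / control)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Box plot of transcript-level fold changes by largest-intron bin
#'
#' @param tx_folds Tibble `transcript_id`, `fold`, optional `knockdown`.
#' @param bins Result of [transcript_intron_size_bins()].
#' @return A ggplot object.
#' @export
plot_transcript_bins <- function(tx_folds, bins) {
  if (!"knockdown" %in% names(tx_folds)) tx_folds$knockdown <- "knockdown"
  df <- tx_folds |> inner_join(bins, by = "transcript_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$fold)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, fill = "grey85") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::facet_wrap(ggplot2::vars(.data$knockdown)) +
    ggplot2::labs(x = "largest intron (kb)",
                  y = "transcript level fold change (knockdown / control)") +
    ggplot2::theme_bw()
}

#' Median-and-p summary plot for a group test
#'
#' @param object A `retention_group_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.retention_group_test <- function(object, ...) {
  df <- tidy(object) |> filter(.data$status == "ok")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$median_fold)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("p=%.2g", .data$p_value)), vjust = -0.4, size = 3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$knockdown)) +
    ggplot2::labs(x = NULL, y = "median fold change") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
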