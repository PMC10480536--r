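#' Box plot of the cohort score distribution with candidates labeled
#'
#' The screening figure: one box over all per-target repeat-read
#' scores, individual targets jittered, outlier candidates labeled.
#'
#' @param object A `telo_ranking` from [rank_and_call()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot telo_ranking
#' @export
autoplot.telo_ranking <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = "cohort", y = .data$score)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.3,
                          fill = "grey90") +
    ggplot2::geom_jitter(width = 0.08, height = 0, size = 1.5,
                         ggplot2::aes(colour = .data$is_outlier)) +
    ggplot2::geom_text(
      data = df[df$is_outlier, , drop = FALSE],
      ggplot2::aes(label = .data$target), hjust = -0.3, size = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = NULL, y = "repeat-read ratio",
                  title = "Cohort repeat-read ratios") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.telo_ranking
#' @param ranking A `telo_ranking`.
#' @export
plot_ranking <- function(ranking, ...) autoplot.telo_ranking(ranking, ...)

#' Bar chart of per-nucleus cofoci-count bins
#'
#' @param object A `telo_cofoci_hist` from [cofoci_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot telo_cofoci_hist
#' @export
autoplot.telo_cofoci_hist <- function(object, ...) {
  df <- as_tibble(object)
  df$bin <- factor(df$bin, levels = df$bin)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "cofoci per nucleus", y = "fraction of nuclei") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.telo_cofoci_hist
#' @param hist A `telo_cofoci_hist`.
#' @export
plot_cofoci_histogram <- function(hist, ...) autoplot.telo_cofoci_hist(hist, ...)

#' Violin plot of relative telomere length (T/S) by group
#'
#' @param ts_table Output of [compute_ts()].
#' @return A ggplot object.
#' @export
plot_ts_distribution <- function(ts_table) {
  check_columns(ts_table, c("group", "t_s"), "T/S table")
  ggplot2::ggplot(ts_table, ggplot2::aes(x = .data$group, y = .data$t_s)) +
    ggplot2::geom_violin(fill = "grey90") +
    ggplot2::geom_jitter(width = 0.08, height = 0, size = 1) +
    ggplot2::labs(x = NULL, y = "relative telomere length (T/S)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
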