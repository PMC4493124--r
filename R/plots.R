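#' Plot an LD decay curve
#'
#' Mean r-squared per physical-distance bin against the bin midpoint (Mb).
#'
#' @param object a `gs_ld_curve` from [ld_decay_curve()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gs_ld_curve <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), !is.na(.data$mean_r2))
  df$mid_mb <- (df$bin_lower + df$bin_upper) / 2 / 1e6
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid_mb, y = .data$mean_r2)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Distance between markers (Mb)",
                  y = expression(mean ~ r^2),
                  title = "LD decay") +
    ggplot2::theme_minimal()
}

#' Plot prediction accuracy over the grid
#'
#' Mean r_MG against training-population size, one line per marker count,
#' faceted by scenario.
#'
#' @param object a `gs_accuracy` tibble from [run_grid()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gs_accuracy <- function(object, ...) {
  s <- summarise_accuracy(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$n_p, y = .data$mean_r_mg,
                                  colour = factor(.data$n_m),
                                  group = factor(.data$n_m))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~scenario, labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(N[P] ~ "(training lines)"),
                  y = expression(mean ~ r[MG]),
                  colour = expression(N[M])) +
    ggplot2::theme_minimal()
}

#' Plot a kinship matrix heat map
#'
#' @param object a `gs_kinship`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gs_kinship <- function(object, ...) {
  ids <- rownames(object)
  df <- tibble(
    line_1 = factor(rep(ids, times = ncol(object)), levels = ids),
    line_2 = factor(rep(ids, each = nrow(object)), levels = ids),
    kinship = as.vector(unclass(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$line_1, y = .data$line_2,
                                   fill = .data$kinship)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "IBS") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
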