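# ggplot2 display helpers for the main result types.

#' Sequence logo plot
#'
#' Letters stacked by height (frequency times column information content),
#' basic residues blue, acidic red.
#'
#' @param logo Tibble from [logo_heights()].
#' @return A ggplot object.
#' @export
plot_logo <- function(logo) {
  dat <- logo |>
    dplyr::filter(!is.na(.data$letter)) |>
    dplyr::arrange(.data$slot, .data$height) |>
    dplyr::group_by(.data$slot) |>
    dplyr::mutate(ymax = cumsum(.data$height),
                  ymin = .data$ymax - .data$height,
                  y = (.data$ymin + .data$ymax) / 2) |>
    dplyr::ungroup() |>
    dplyr::mutate(class = dplyr::case_when(
      .data$letter %in% c("R", "K", "H") ~ "basic",
      .data$letter %in% c("D", "E") ~ "acidic",
      TRUE ~ "other"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$slot, y = .data$y,
                                    label = .data$letter)) +
    ggplot2::geom_text(ggplot2::aes(size = .data$height,
                                    colour = .data$class),
                       fontface = "bold", show.legend = FALSE) +
    ggplot2::scale_size(range = c(1, 10)) +
    ggplot2::scale_colour_manual(values = c(basic = "#2166ac",
                                            acidic = "#b2182b",
                                            other = "grey30")) +
    ggplot2::scale_x_continuous(breaks = unique(dat$slot)) +
    ggplot2::labs(x = "motif slot", y = "information (bits)") +
    ggplot2::theme_minimal()
}

#' Plot a sequence similarity network
#'
#' Force-directed layout of representatives; node size scales with member
#' count, colour with phylum when taxonomy is present.
#'
#' @param network An `ssn`.
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_ssn <- function(network, seed = 1L) {
  g <- ssn_graph(network)
  xy <- with_seed(seed, igraph::layout_with_fr(g))
  nodes <- dplyr::mutate(network$nodes, x = xy[, 1], y = xy[, 2])
  edges <- network$edges |>
    dplyr::left_join(dplyr::select(nodes, "id", x1 = "x", y1 = "y"),
                     by = c(from = "id")) |>
    dplyr::left_join(dplyr::select(nodes, "id", x2 = "x", y2 = "y"),
                     by = c(to = "id"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x1, y = .data$y1,
                                       xend = .data$x2, yend = .data$y2),
                          colour = "grey70", linewidth = 0.3)
  if ("phylum" %in% names(nodes)) {
    p <- p + ggplot2::geom_point(
      data = nodes, ggplot2::aes(x = .data$x, y = .data$y,
                                 size = .data$n_members,
                                 colour = .data$phylum))
  } else {
    p <- p + ggplot2::geom_point(
      data = nodes, ggplot2::aes(x = .data$x, y = .data$y,
                                 size = .data$n_members))
  }
  p + ggplot2::theme_void()
}

#' Progress curves with fitted model overlay
#'
#' @param object A `progress_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.progress_fit <- function(object, ...) {
  dat <- object$residuals
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t_s, colour = .data$curve_id)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$P_uM), size = 0.6,
                        alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::labs(x = "time (s)", y = "product (µM)",
                  colour = "curve") +
    ggplot2::theme_minimal()
}

#' MCMC trace plot
#'
#' @param run An `mcmc_run`.
#' @return A ggplot object of per-chain log-likelihood traces.
#' @export
plot_traces <- function(run) {
  tidy(run) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$sample, y = .data$loglik,
                                 colour = factor(.data$chain))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(colour = "chain", y = "log-likelihood") +
    ggplot2::theme_minimal()
}
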