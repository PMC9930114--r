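# Plotting helpers. All positions shown on plots are 1-based (file exports
# are 0-based half-open; both conventions are documented in the IO help).

#' Kernel density overlay of per-chain compositions
#'
#' One density curve per monomer of the per-chain mole-fraction
#' distribution — the chemical-heterogeneity view of a batch.
#'
#' @param batch an `rhp_batch`.
#' @return A ggplot object.
#' @export
plot_composition_kde <- function(batch) {
  comp <- chain_compositions(batch)
  curves <- do.call(rbind, lapply(names(comp), function(sym) {
    d <- kde_fwhm(comp[[sym]])$density
    d$monomer <- sym
    d
  }))
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$x, y = .data$y,
                                       color = .data$monomer)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "per-chain mole fraction", y = "density",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter-line plot of nFWHM profiles
#'
#' Plots feed-normalized FWHM per monomer across a series of batches (e.g.
#' varying NC or DP) as a scatter-line.
#'
#' @param profiles data.frame from rbinding [nfwhm_profile()] outputs, with
#'   an extra column named by `x` identifying each batch.
#' @param x name of the batch-identifying column (default `"batch"`).
#' @return A ggplot object.
#' @export
plot_nfwhm <- function(profiles, x = "batch") {
  ggplot2::ggplot(profiles, ggplot2::aes(x = .data[[x]], y = .data$nfwhm,
                                         color = .data$symbol,
                                         group = .data$symbol)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(y = "nFWHM", color = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of a segment length distribution
#'
#' @param dist a distribution data.frame (`length`, `value`).
#' @param highlight segment lengths to emphasize (defaults 1, 3, 5, 10, the
#'   conventional hydrophobic-segment report set; motif reports typically
#'   use 5, 8, 10, 13).
#' @return A ggplot object.
#' @export
plot_segment_distribution <- function(dist, highlight = c(1, 3, 5, 10)) {
  dist$highlight <- dist$length %in% highlight
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$length, y = .data$value,
                                     fill = .data$highlight)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "steelblue")) +
    ggplot2::labs(x = "segment length (monomers)", y = "frequency") +
    ggplot2::theme_minimal()
}

#' Hydropathy plot of one chain
#'
#' Window-averaged HLB versus center position, with the classification
#' threshold drawn as a horizontal line.
#'
#' @param profile a [window_profile()].
#' @param threshold HLB cutoff line (default 9).
#' @return A ggplot object.
#' @export
plot_hydropathy <- function(profile, threshold = 9) {
  df <- data.frame(position = attr(profile, "positions"),
                   hlb = as.numeric(profile))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$hlb)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "position (alpha end = 1)",
                  y = "window-averaged HLB") +
    ggplot2::theme_minimal()
}

#' Positionwise window-HLB statistics plot
#'
#' Batch mean window HLB per position with a +/- 1 sd ribbon; the ribbon
#' widens toward the omega end, where polydispersity thins the contributor
#' count.
#'
#' @param stats output of [batch_position_stats()].
#' @return A ggplot object.
#' @export
plot_position_stats <- function(stats) {
  df <- stats$per_position
  df$sd <- sqrt(df$var)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (alpha end = 1)",
                  y = "window-averaged HLB") +
    ggplot2::theme_minimal()
}
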