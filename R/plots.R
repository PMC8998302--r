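#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot single-cell fluorescence traces
#'
#' Spaghetti plot of per-cell traces, faceted by stimulus, with the
#' stimulus application time marked. Useful for eyeballing kernel shapes
#' (transient P2X3, sustained KCl) and noise levels.
#'
#' @param traces Long-format trace tibble.
#' @param wells Wells to plot; defaults to the first well.
#' @param n_cells Number of cells sampled per recording (deterministic:
#'   the first `n_cells` by id).
#' @param baseline_end_s Stimulus application time marker (s).
#' @return A ggplot object.
#' @export
plot_traces <- function(traces, wells = NULL, n_cells = 20,
                        baseline_end_s = 10) {
  traces <- tibble::as_tibble(traces)
  wells <- wells %||% traces$well_id[1]
  d <- dplyr::filter(traces, .data$well_id %in% wells)
  keep <- sort(unique(d$cell_id))[seq_len(min(n_cells,
                                              dplyr::n_distinct(d$cell_id)))]
  d <- dplyr::filter(d, .data$cell_id %in% keep)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$fluorescence_au,
                                  group = .data$cell_id)) +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = baseline_end_s, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$stimulus)) +
    ggplot2::labs(x = "Time (s)", y = "Fluorescence (a.u.)",
                  title = paste("Well", paste(wells, collapse = ", "))) +
    ggplot2::theme_bw()
}

#' @describeIn fit_curve Concentration-response plot: biological-replicate
#'   means, the fitted curve, and the 90% cytotoxicity / 75% neurite-effect
#'   threshold lines.
#' @param object A `"dr_fit"` object.
#' @method autoplot dr_fit
#' @export
autoplot.dr_fit <- function(object, ...) {
  d <- object$bio_means
  nz <- d$concentration_nM[d$concentration_nM > 0]
  # plot the control at a pseudo-concentration one log-step below the lowest
  pseudo0 <- min(nz) / 10
  d$conc_plot <- ifelse(d$concentration_nM == 0, pseudo0, d$concentration_nM)
  grid <- exp(seq(log(pseudo0), log(max(nz)), length.out = 120))
  curve <- tibble::tibble(
    conc_plot = grid,
    value = predict(object, ifelse(grid <= pseudo0, 0, grid))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$conc_plot, y = .data$value)) +
    ggplot2::geom_hline(yintercept = c(90, 75), linetype = "dashed",
                        colour = c("red3", "grey40")) +
    ggplot2::geom_point(shape = 1) +
    ggplot2::geom_line(data = curve) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Concentration (nM, control at left edge)",
                  y = "% of untreated control",
                  title = paste(object$compound, object$endpoint,
                                sep = " — ")) +
    ggplot2::theme_bw()
}

#' Plot an attenuation profile
#'
#' Bar chart of responsive fractions as % of untreated control with SEM
#' error bars over biological replicates, by condition and stimulus.
#'
#' @param profile Output of [attenuation_profile()].
#' @return A ggplot object.
#' @export
plot_attenuation <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$condition,
                                        y = .data$pct_of_control)) +
    ggplot2::geom_col(fill = "grey70", colour = "black") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$pct_of_control - .data$sem_pct,
                   ymax = .data$pct_of_control + .data$sem_pct),
      width = 0.2) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$stimulus)) +
    ggplot2::labs(x = NULL, y = "Responsive cells (% of untreated control)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
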