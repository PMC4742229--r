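#' Multi-dimensional sensitivity distribution (MDSD) plot
#'
#' Summarizes a sensitivity tensor as a grid of panels: one row per output
#' (ranked by mean sensitivity, largest on top), one column per input
#' (ranked most to least influential). Each panel holds one vertical
#' histogram column per sampling range, with grayscale intensity
#' proportional to the within-column relative frequency of sensitivity
#' values (darkest = most common). Consistent input-output effects appear
#' as dark narrow bands; negligible ones as narrow bands at zero; erratic
#' ones as diffuse columns.
#'
#' @param tensor A `"vp_tensor"`, possibly spanning several `rmax` values.
#' @param n_bins Number of vertical histogram bins per panel column.
#' @param clip Quantile pair used to clip the sensitivity axis per output
#'   row (unbounded outliers would otherwise flatten the grayscale).
#' @return A ggplot object. The underlying binned data can be recovered
#'   with `ggplot2::ggplot_build()` or by calling [mdsd_data()] directly.
#' @export
plot_mdsd <- function(tensor, n_bins = 50L, clip = c(0.01, 0.99)) {
  dat <- mdsd_data(tensor, n_bins, clip)
  ggplot(dat, aes(x = factor(.data$rmax), y = .data$s_mid,
                  fill = .data$rel_freq)) +
    geom_tile(width = 0.9, height = dat$bin_width) +
    scale_fill_gradient(low = "white", high = "black",
                        name = "relative\nfrequency") +
    facet_grid(rows = vars(.data$output_f), cols = vars(.data$input_f),
               scales = "free_y") +
    labs(x = "sampling range (Rmax)", y = "non-dimensional sensitivity S*") +
    theme_minimal(base_size = 9) +
    theme(panel.grid = element_blank(),
          strip.text.x = element_text(face = "bold"))
}

#' Binned data behind the MDSD plot
#'
#' @inheritParams plot_mdsd
#' @return Tibble: `input`, `output`, `rmax`, `s_mid` (bin centre),
#'   `bin_width`, `rel_freq` (sums to 1 within each input-output-rmax
#'   column), plus ranked factor columns `input_f`, `output_f`.
#' @export
mdsd_data <- function(tensor, n_bins = 50L, clip = c(0.01, 0.99)) {
  stopifnot(nrow(tensor) > 0)
  valid <- dplyr::filter(tensor, .data$valid)
  if (!nrow(valid)) stop("no valid sensitivity records to plot")

  input_order <- valid |>
    dplyr::group_by(.data$input) |>
    dplyr::summarise(infl = mean(abs(.data$s_star)), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$infl)) |>
    dplyr::pull(.data$input)
  output_order <- valid |>
    dplyr::group_by(.data$output) |>
    dplyr::summarise(ms = mean(abs(.data$s_star)), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$ms)) |>
    dplyr::pull(.data$output)

  valid |>
    dplyr::group_by(.data$output) |>
    dplyr::group_modify(function(df, key) {
      lims <- quantile(df$s_star, clip, names = FALSE)
      if (lims[1] == lims[2]) lims <- lims + c(-0.5, 0.5)
      edges <- seq(lims[1], lims[2], length.out = n_bins + 1L)
      width <- diff(edges[1:2])
      df |>
        dplyr::mutate(s_clip = pmin(pmax(.data$s_star, lims[1]), lims[2]),
                      bin = pmin(findInterval(.data$s_clip, edges,
                                              rightmost.closed = TRUE),
                                 n_bins)) |>
        dplyr::count(.data$input, .data$rmax, .data$bin, name = "n") |>
        dplyr::group_by(.data$input, .data$rmax) |>
        dplyr::mutate(rel_freq = .data$n / sum(.data$n),
                      s_mid = edges[.data$bin] + width / 2,
                      bin_width = width) |>
        dplyr::ungroup()
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      input_f = factor(.data$input, levels = input_order),
      output_f = factor(.data$output, levels = output_order))
}

#' Mean versus standard deviation of pair sensitivities
#'
#' Scatter of the population mean against the population standard
#' deviation of `S*` for each input-output pair at a single sampling
#' range. Shaded wedges mark pairs whose mean is smaller than one (dark
#' grey) or two (light grey) standard deviations -- effects that are not
#' reliably of one sign across the population. Points outside the shading
#' are labelled: those effects are consistent across virtually all
#' subjects.
#'
#' @param summaries Per-range summary from
#'   `summarize_pairs(tensor, by_range = TRUE)` filtered to one `rmax`
#'   (or containing a single `rmax`).
#' @return A ggplot object.
#' @export
plot_mean_sd <- function(summaries) {
  stopifnot(all(c("mean", "sd", "input", "output") %in% names(summaries)))
  if ("rmax" %in% names(summaries) && length(unique(summaries$rmax)) != 1L)
    stop("plot_mean_sd expects summaries at a single rmax; filter first")
  lim <- max(abs(summaries$mean), na.rm = TRUE) * 1.1
  sd_max <- max(summaries$sd, na.rm = TRUE) * 1.15
  wedge2 <- data.frame(x = c(-2 * sd_max, 0, 2 * sd_max),
                       y = c(sd_max, 0, sd_max))
  wedge1 <- data.frame(x = c(-sd_max, 0, sd_max),
                       y = c(sd_max, 0, sd_max))
  lab <- dplyr::filter(summaries, abs(.data$mean) >= 2 * .data$sd)
  ggplot(summaries, aes(x = .data$mean, y = .data$sd)) +
    geom_polygon(data = wedge2, aes(x = .data$x, y = .data$y),
                 fill = "grey85", inherit.aes = FALSE) +
    geom_polygon(data = wedge1, aes(x = .data$x, y = .data$y),
                 fill = "grey60", inherit.aes = FALSE) +
    geom_point(size = 1.6) +
    geom_text(data = lab,
              aes(label = paste(.data$input, "→", .data$output)),
              vjust = -0.7, size = 2.7) +
    coord_cartesian(xlim = c(-lim, lim), ylim = c(0, sd_max)) +
    labs(x = "mean sensitivity", y = "standard deviation of sensitivity") +
    theme_classic(base_size = 10)
}

#' Success-rate curves across sampling ranges
#'
#' Acceptance rate of the normal-phonation filter as a function of the
#' sampling range bound, for uniform sampling (solid) and, optionally,
#' adaptive density-based resampling (dashed).
#'
#' @param rates Tibble with columns `rmax`, `success_rate` and `method`
#'   (`"uniform"` / `"adaptive"`); at least two `rmax` points.
#' @return A ggplot object (y axis on a log scale).
#' @export
plot_success <- function(rates) {
  stopifnot(all(c("rmax", "success_rate", "method") %in% names(rates)))
  if (length(unique(rates$rmax)) < 2L)
    stop("need success rates at >= 2 rmax values to draw a trend")
  ggplot(rates, aes(x = .data$rmax, y = .data$success_rate,
                    linetype = .data$method)) +
    geom_line() +
    geom_point() +
    scale_linetype_manual(values = c(uniform = "solid", adaptive = "dashed")) +
    scale_y_log10(labels = function(x) paste0(100 * x, "%")) +
    labs(x = "sampling range (Rmax)", y = "normal-phonation success rate",
         linetype = NULL) +
    theme_classic(base_size = 10)
}

#' Per-parameter success histograms plot
#'
#' Normalized-factor histograms of the accepted population, one panel per
#' input parameter on the log-factor axis. Near-uniform panels indicate
#' parameters that barely affect the chance of normal phonation.
#'
#' @param hists Tibble from [success_histograms()].
#' @return A ggplot object.
#' @export
plot_success_histograms <- function(hists) {
  ggplot(hists, aes(x = (.data$log_lo + .data$log_hi) / 2, y = .data$mass)) +
    geom_col(width = hists$log_hi - hists$log_lo, fill = "grey30") +
    facet_wrap(vars(.data$parameter), scales = "free_y") +
    labs(x = "log normalized factor", y = "relative frequency") +
    theme_minimal(base_size = 9)
}

#' @export
autoplot.vp_tensor <- function(object, ...) plot_mdsd(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
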