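#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col
#'   scale_fill_viridis_c labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a bivariate FUNC-CLD as a filled raster
#'
#' @param object A `func_cld`.
#' @param trans Fill transformation (default `"sqrt"` to open up the tails).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.func_cld <- function(object, trans = "sqrt", ...) {
  ggplot(object, aes(x = .data$cl, y = .data$func, fill = .data$fraction)) +
    ggplot2::geom_tile() +
    scale_fill_viridis_c(trans = trans, name = "number\nfraction") +
    labs(x = "chain length CL", y = "functional units FUNC",
         title = "Functionality-chain-length distribution") +
    theme_minimal()
}

#' Plot conversion, averages and side-product fractions along a trajectory
#'
#' @param object A `kmc_trajectory`.
#' @param ... Unused.
#' @return A ggplot of per-monomer conversion vs time, with macromonomer
#'   and branched fractions vs overall conversion available via
#'   [plot_species_fractions()].
#' @export
autoplot.kmc_trajectory <- function(object, ...) {
  s <- tidyr::pivot_longer(object$snapshots,
                           c("conversion_m1", "conversion_m2"),
                           names_to = "monomer", values_to = "x")
  ggplot(s, aes(x = .data$time, y = .data$x, colour = .data$monomer)) +
    geom_line() +
    labs(x = "time (s)", y = "conversion",
         title = "Per-monomer conversion") +
    theme_minimal()
}

#' @rdname autoplot.kmc_trajectory
#' @param traj A `kmc_trajectory`.
#' @export
plot_species_fractions <- function(traj) {
  s <- tidyr::pivot_longer(traj$snapshots,
                           c("macromonomer_fraction", "branched_fraction"),
                           names_to = "species", values_to = "fraction")
  ggplot(s, aes(x = .data$conversion, y = .data$fraction,
                colour = .data$species)) +
    geom_line() +
    labs(x = "overall conversion", y = "number fraction") +
    theme_minimal()
}

#' Bar plot of a functionality distribution with its quality color
#'
#' @param funcd Tibble `func`, `fraction`.
#' @param thresholds A [quality_thresholds()].
#' @return A ggplot; the bar fill is the five-band quality color of the
#'   distribution.
#' @export
plot_funcd <- function(funcd, thresholds = quality_thresholds()) {
  m <- funcd_moments(funcd)
  cv <- if (m$mu > 0) m$sigma / m$mu else NA_real_
  lab <- classify_quality(cv, fraction_nonfunctionalized(funcd), thresholds)
  fill <- c(dark_green = "#1a9850", light_green = "#91cf60",
            yellow = "#fee08b", orange = "#fc8d59",
            dark_red = "#d73027")[as.character(lab)]
  ggplot(funcd, aes(x = .data$func, y = .data$fraction)) +
    geom_col(fill = fill) +
    labs(x = "functional units FUNC", y = "number fraction",
         subtitle = sprintf("C_v = %.3f, f_nonfunctionalized = %.4f: %s",
                            cv, fraction_nonfunctionalized(funcd), lab)) +
    theme_minimal()
}
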