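#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a droplet shrinkage series
#'
#' Radii of both droplets against time; the contact radius is drawn as a
#' dashed reference line.
#'
#' @param object A `shrinkage_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.shrinkage_series <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("R1_um", "R2_um"),
                              names_to = "droplet", values_to = "radius_um")
  ggplot2::ggplot(long, ggplot2::aes(.data$t_s, .data$radius_um,
                                     colour = .data$droplet)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(.data$t_s, .data$r_um),
                       data = as_tibble(object),
                       linetype = "dashed", inherit.aes = FALSE) +
    ggplot2::labs(x = "time (s)", y = "radius (µm)",
                  colour = NULL,
                  title = "Osmotic droplet shrinkage")
}

#' Plot an excess heat-capacity curve
#'
#' @param object A `cp_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cp_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$T_C, .data$cp_kcal_mol_C)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "temperature (°C)",
                  y = expression(C[p] ~ "(kcal" ~ mol^-1 ~ degree * C^-1 * ")"),
                  title = "Excess heat capacity")
}

#' Plot a Raman spectrum
#'
#' @param object A `raman_spectrum`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.raman_spectrum <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$wavenumber_cm1, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression("Raman shift (" * cm^-1 * ")"),
                  y = "intensity (a.u.)",
                  title = attr(object, "label") %||% "Raman spectrum")
}

#' Plot order ratios against aspirin fraction
#'
#' @param data A tibble with columns `chi_asa`, `pH`, `r_sym_asym`,
#'   `r_term_asym` (e.g. the `raman` table of [study_report()]).
#' @return A ggplot object, one panel per ratio, coloured by pH.
#' @export
plot_order_ratios <- function(data) {
  long <- tidyr::pivot_longer(data, c("r_sym_asym", "r_term_asym"),
                              names_to = "ratio", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$chi_asa, .data$value,
                                     colour = factor(.data$pH))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~ratio, scales = "free_y",
                        labeller = ggplot2::as_labeller(c(
                          r_sym_asym = "I(2848)/I(2890)",
                          r_term_asym = "I(2930)/I(2890)"))) +
    ggplot2::labs(x = expression(chi[ASA]), y = "intensity ratio",
                  colour = "pH")
}
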