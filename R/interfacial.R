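#' Contact angle of two adhering droplets
#'
#' Computes the bilayer contact angle of a droplet interface bilayer (DIB)
#' from the radii of the two droplets and the radius of their contact zone,
#' using the mean half-angle of the two contacting spherical caps:
#' \deqn{\theta = \tfrac{1}{2}\left[\arcsin(r/R_1) + \arcsin(r/R_2)\right]}
#'
#' The angle is symmetric in the two droplet radii and increases
#' monotonically with the contact radius at fixed droplet radii.
#'
#' @param R1,R2 Droplet radii (micrometres). Must be positive.
#' @param r Radius of the inter-droplet contact zone (micrometres).
#'   Must satisfy `0 <= r <= min(R1, R2)`.
#'
#' @return Contact angle in degrees, in `[0, 90]`. Vectorised over inputs.
#' @examples
#' contact_angle(100, 100, 50)  # arcsin(1/2) = 30 degrees
#' @seealso [bilayer_tension()], [formation_free_energy()]
#' @export
contact_angle <- function(R1, R2, r) {
  check_contact_geometry(R1, R2, r)
  rad2deg(0.5 * (asin(r / R1) + asin(r / R2)))
}

check_contact_geometry <- function(R1, R2, r) {
  if (any(!is.finite(R1)) || any(!is.finite(R2)) || any(!is.finite(r))) {
    stop_geometry("droplet geometry must be finite")
  }
  if (any(R1 <= 0) || any(R2 <= 0)) {
    stop_geometry("droplet radii must be positive")
  }
  if (any(r < 0) || any(r > pmin(R1, R2))) {
    stop_geometry("contact radius must satisfy 0 <= r <= min(R1, R2)")
  }
  invisible(TRUE)
}

check_tension_inputs <- function(gamma_m, theta) {
  if (any(!is.finite(gamma_m)) || any(gamma_m <= 0)) {
    stop_domain("monolayer tension gamma_m must be positive")
  }
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta >= 90)) {
    stop_domain("contact angle theta must lie in [0, 90) degrees")
  }
  invisible(TRUE)
}

#' Bilayer tension from monolayer tension and contact angle
#'
#' The tension of the contact-zone bilayer follows from a force balance at
#' the three-phase contact line of the two adherent monolayers:
#' \deqn{\gamma_B = 2\,\gamma_m \cos\theta}
#'
#' @param gamma_m Monolayer interfacial tension at the oil-lipid-water
#'   interface (mN/m), positive.
#' @param theta Contact angle between the droplets (degrees), in `[0, 90)`.
#'
#' @return Bilayer tension in mN/m, in `(0, 2 gamma_m]`. Vectorised.
#' @examples
#' bilayer_tension(1.12, 36.7)  # 1.80 mN/m for a DOPC DIB
#' @export
bilayer_tension <- function(gamma_m, theta) {
  check_tension_inputs(gamma_m, theta)
  2 * gamma_m * cos(deg2rad(theta))
}

#' Young-Dupre free energy of bilayer formation
#'
#' Adhesion energy per unit bilayer area released when the two apposing
#' monolayers zip into a bilayer:
#' \deqn{\Delta F = 2\,\gamma_m (\cos\theta - 1) \le 0}
#' The signed value is returned; reports conventionally quote its absolute
#' value, which equals `2 * gamma_m - bilayer_tension(gamma_m, theta)`
#' identically.
#'
#' @inheritParams bilayer_tension
#' @return Signed formation free energy in mJ/m^2 (non-positive). Vectorised.
#' @examples
#' abs(formation_free_energy(1.12, 36.7))  # 0.445 mJ/m^2
#' @export
formation_free_energy <- function(gamma_m, theta) {
  check_tension_inputs(gamma_m, theta)
  2 * gamma_m * (cos(deg2rad(theta)) - 1)
}

#' Relative membrane lateral pressure
#'
#' \deqn{\pi = \gamma_m (1 - \cos\theta)}
#' Numerically half the magnitude of the formation free energy.
#'
#' @inheritParams bilayer_tension
#' @return Lateral pressure in mN/m (non-negative). Vectorised.
#' @export
lateral_pressure <- function(gamma_m, theta) {
  check_tension_inputs(gamma_m, theta)
  gamma_m * (1 - cos(deg2rad(theta)))
}

#' Derived interfacial parameters for a table of DIB measurements
#'
#' Takes a data frame of per-condition measurements and returns the full set
#' of derived interfacial parameters.  Two input layouts are accepted:
#'
#' * columns `gamma_m` and `theta` (monolayer tension in mN/m, contact angle
#'   in degrees), or
#' * columns `gamma_m`, `R1`, `R2`, `r` (droplet geometry in micrometres),
#'   from which the contact angle is computed with [contact_angle()].
#'
#' Any other columns (labels, compositions) are carried through unchanged.
#'
#' @param data A data frame, one row per condition.
#' @param rounded If `TRUE`, round the derived columns to reporting
#'   precision: tension to 2 decimals, energies to 3 decimals.
#' @return A tibble with the input columns plus `theta_deg`, `gamma_B_mN_m`,
#'   `delta_F_mJ_m2` (signed), `abs_delta_F_mJ_m2` and
#'   `lateral_pressure_mN_m`.
#' @examples
#' interfacial_params(
#'   data.frame(label = c("1:0", "1:1"),
#'              gamma_m = c(1.12, 0.92), theta = c(36.7, 25.9)),
#'   rounded = TRUE)
#' @export
interfacial_params <- function(data, rounded = FALSE) {
  data <- as_tibble(data)
  if (!"gamma_m" %in% names(data)) {
    stop_domain("input table must contain a 'gamma_m' column (mN/m)")
  }
  if ("theta" %in% names(data)) {
    theta <- data$theta
  } else if (all(c("R1", "R2", "r") %in% names(data))) {
    theta <- contact_angle(data$R1, data$R2, data$r)
  } else {
    stop_domain(
      "input table needs either a 'theta' column or 'R1', 'R2', 'r' columns")
  }
  out <- dplyr::mutate(
    data,
    theta_deg = theta,
    gamma_B_mN_m = bilayer_tension(.data$gamma_m, theta),
    delta_F_mJ_m2 = formation_free_energy(.data$gamma_m, theta),
    abs_delta_F_mJ_m2 = abs(.data$delta_F_mJ_m2),
    lateral_pressure_mN_m = lateral_pressure(.data$gamma_m, theta)
  )
  if (rounded) {
    out <- dplyr::mutate(
      out,
      gamma_B_mN_m = round(.data$gamma_B_mN_m, 2),
      delta_F_mJ_m2 = round(.data$delta_F_mJ_m2, 3),
      abs_delta_F_mJ_m2 = round(.data$abs_delta_F_mJ_m2, 3),
      lateral_pressure_mN_m = round(.data$lateral_pressure_mN_m, 3)
    )
  }
  out
}
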