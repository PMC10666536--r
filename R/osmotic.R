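#' Convert osmolality to an osmotic concentration
#'
#' Maps a measured osmolality (mOsm per kg of water) onto the molar
#' concentration that drives osmotic volume flow, under the dilute-solution
#' convention that 1 kg of water occupies 1 L: 1 mOsm/kg maps to 1 mol/m^3.
#'
#' @param osmolality Osmolality in mOsm/kg, non-negative. Vectorised.
#' @return Concentration in mol/m^3.
#' @export
osmolality_to_concentration <- function(osmolality) {
  if (any(!is.finite(osmolality)) || any(osmolality < 0)) {
    stop_domain("osmolality must be finite and non-negative")
  }
  osmolality
}

cap_height <- function(R, r) R - sqrt(R^2 - r^2)

spherical_cap_volume <- function(R, r) {
  h <- cap_height(R, r)
  pi * h^2 * (R - h / 3)
}

#' Droplet volumes from observed radii
#'
#' Reconstructs droplet volumes from the radii of a droplet pair and their
#' contact radius.  In `"sphere"` mode each droplet is taken as a full
#' sphere, `V = (4/3) pi R^3`; in `"truncated"` mode the spherical cap cut
#' off by the contact plane is removed, `V = (4/3) pi R^3 - pi h^2 (R - h/3)`
#' with cap height `h = R - sqrt(R^2 - r^2)`.  The truncated volume is never
#' larger than the sphere volume and the two agree as `r -> 0`.
#'
#' @inheritParams contact_angle
#' @param mode Either `"sphere"` (default) or `"truncated"`.
#' @return A list with numeric vectors `V1` and `V2` (cubic micrometres).
#' @export
volumes_from_radii <- function(R1, R2, r, mode = c("sphere", "truncated")) {
  mode <- match.arg(mode)
  check_contact_geometry(R1, R2, r)
  V1 <- 4 / 3 * pi * R1^3
  V2 <- 4 / 3 * pi * R2^3
  if (mode == "truncated") {
    V1 <- V1 - spherical_cap_volume(R1, r)
    V2 <- V2 - spherical_cap_volume(R2, r)
  }
  list(V1 = V1, V2 = V2)
}

# invert volumes_from_radii for one droplet at fixed contact radius
radius_from_volume <- function(V, r = 0, mode = "sphere") {
  R_sphere <- (3 * V / (4 * pi))^(1 / 3)
  if (mode == "sphere" || r == 0) {
    return(R_sphere)
  }
  vapply(seq_along(V), function(i) {
    f <- function(R) {
      4 / 3 * pi * R^3 - spherical_cap_volume(R, r) - V[i]
    }
    lo <- max(R_sphere[i], r * (1 + 1e-12))
    hi <- 2 * R_sphere[i] + r
    while (f(hi) < 0) hi <- hi * 2
    uniroot(f, c(lo, hi), tol = 1e-10)$root
  }, numeric(1))
}

#' Initial state of an osmotically unbalanced droplet pair
#'
#' Bundles the state variables of the closed two-droplet system: volumes,
#' osmotically active solute amounts (held constant over time; water is the
#' only permeant), and the bilayer contact area.
#'
#' @param V1,V2 Droplet volumes (um^3), positive.
#' @param osmolality1,osmolality2 Initial osmolalities of the two droplets
#'   (mOsm/kg), non-negative.
#' @param A Bilayer contact area (um^2), non-negative.
#' @return An object of class `droplet_pair_state`: a list with `V1`, `V2`,
#'   `n1`, `n2` (solute amounts, mol um^3 / m^3), and `A`.
#' @export
droplet_pair_state <- function(V1, V2, osmolality1, osmolality2, A) {
  if (V1 <= 0 || V2 <= 0) stop_domain("droplet volumes must be positive")
  if (A < 0) stop_domain("contact area must be non-negative")
  c1 <- osmolality_to_concentration(osmolality1)
  c2 <- osmolality_to_concentration(osmolality2)
  structure(
    list(V1 = V1, V2 = V2, n1 = c1 * V1, n2 = c2 * V2, A = A,
         osmolality1 = osmolality1, osmolality2 = osmolality2),
    class = "droplet_pair_state"
  )
}

#' Simulate osmotic shrinkage of a droplet pair
#'
#' Integrates the standard osmotic volume-flow law for water transport
#' through the droplet interface bilayer,
#' \deqn{dV_1/dt = P_f \, V_w \, A \, (c_1 - c_2), \qquad dV_2/dt = -dV_1/dt,}
#' where `c_i = n_i / V_i` are the instantaneous osmotic concentrations and
#' `V_w` is the molar volume of water.  The two-droplet system is closed:
#' only `V1` is integrated and `V2 = V_tot - V1`, so total volume is
#' conserved exactly.  Solutes do not permeate.  The contact area is held at
#' its initial value by default (shrinkage is small over typical measurement
#' windows); with `area_mode = "contact_angle"` the area is recomputed each
#' sample from a fixed contact angle.
#'
#' Radii are back-computed from volumes with the same geometry mode used by
#' [volumes_from_radii()], then optionally corrupted with multiplicative
#' Gaussian noise (image-analysis error scales with droplet size).
#'
#' @param state0 A [droplet_pair_state()].
#' @param pf Osmotic water permeability coefficient (um/s), non-negative.
#' @param t_end End of the sampled window (s).
#' @param dt Sampling interval (s); this is the output grid, not the solver
#'   step (the solver is adaptive).
#' @param noise_sd Relative standard deviation of multiplicative Gaussian
#'   noise applied to the radii; `0` gives a deterministic series.
#' @param seed Integer seed; required whenever `noise_sd > 0`.
#' @param geometry_mode `"sphere"` or `"truncated"`, used for the
#'   volume-to-radius back-computation.
#' @param area_mode `"fixed"` (default) or `"contact_angle"`.
#' @return A `shrinkage_series` tibble with columns `t_s`, `R1_um`, `R2_um`,
#'   `r_um`, carrying the initial osmolalities, the true `pf`, and the
#'   geometry mode as attributes.
#' @examples
#' st <- droplet_pair_state(V1 = 1.4e7, V2 = 1.4e7,
#'                          osmolality1 = 300, osmolality2 = 100, A = 1e4)
#' ser <- simulate_droplet_pair(st, pf = 70, t_end = 200, dt = 10)
#' @export
simulate_droplet_pair <- function(state0, pf, t_end, dt,
                                  noise_sd = 0, seed = NULL,
                                  geometry_mode = c("sphere", "truncated"),
                                  area_mode = c("fixed", "contact_angle")) {
  geometry_mode <- match.arg(geometry_mode)
  area_mode <- match.arg(area_mode)
  stopifnot(inherits(state0, "droplet_pair_state"))
  if (pf < 0) stop_domain("pf must be non-negative")
  if (dt <= 0 || t_end <= 0) stop_domain("t_end and dt must be positive")
  if (noise_sd < 0) stop_domain("noise_sd must be non-negative")
  if (noise_sd > 0 && is.null(seed)) {
    stop_domain("a seed is required when noise_sd > 0")
  }

  vtot <- state0$V1 + state0$V2
  n1 <- state0$n1
  n2 <- state0$n2
  r0 <- sqrt(state0$A / pi)
  theta0 <- NULL
  if (area_mode == "contact_angle") {
    R10 <- radius_from_volume(state0$V1, r0, geometry_mode)
    theta0 <- contact_angle(R10, radius_from_volume(state0$V2, r0,
                                                    geometry_mode), r0)
  }

  deriv <- function(t, y, parms) {
    V1 <- y[1]
    V2 <- vtot - V1
    A <- if (area_mode == "fixed") {
      state0$A
    } else {
      # fixed contact angle: r = R * sin(theta) for the smaller droplet
      Rm <- (3 * min(V1, V2) / (4 * pi))^(1 / 3)
      pi * (Rm * sin(deg2rad(theta0)))^2
    }
    list(pf * .kv_flux * A * (n1 / V1 - n2 / V2))
  }
  times <- seq(0, t_end, by = dt)
  sol <- deSolve::ode(y = c(V1 = state0$V1), times = times, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-6)
  V1 <- sol[, "V1"]
  V2 <- vtot - V1
  if (any(V1 <= 0) || any(V2 <= 0)) {
    abort("osmotic flow drove a droplet volume non-positive; shorten t_end",
          class = "dibkit_domain_error")
  }

  r_series <- rep(r0, length(times))
  if (area_mode == "contact_angle") {
    Rm <- (3 * pmin(V1, V2) / (4 * pi))^(1 / 3)
    r_series <- Rm * sin(deg2rad(theta0))
  }
  R1 <- radius_from_volume(V1, r0, geometry_mode)
  R2 <- radius_from_volume(V2, r0, geometry_mode)
  if (noise_sd > 0) {
    set.seed(seed)
    R1 <- R1 * (1 + rnorm(length(R1), 0, noise_sd))
    R2 <- R2 * (1 + rnorm(length(R2), 0, noise_sd))
  }
  out <- tibble(t_s = times, R1_um = R1, R2_um = R2, r_um = r_series)
  new_shrinkage_series(out,
                       osmolality1 = state0$osmolality1,
                       osmolality2 = state0$osmolality2,
                       geometry_mode = geometry_mode,
                       true_pf = pf, seed = seed, noise_sd = noise_sd,
                       state0 = state0)
}

new_shrinkage_series <- function(data, osmolality1, osmolality2,
                                 geometry_mode = "sphere", true_pf = NULL,
                                 seed = NULL, noise_sd = NULL,
                                 state0 = NULL, composition = NULL) {
  out <- as_tibble(data)
  if (is.unsorted(out$t_s, strictly = TRUE)) {
    stop_domain("sample times must be strictly increasing")
  }
  if (any(out$R1_um <= 0) || any(out$R2_um <= 0)) {
    stop_domain("radii must be positive")
  }
  structure(out,
            class = c("shrinkage_series", class(out)),
            osmolality1 = osmolality1, osmolality2 = osmolality2,
            geometry_mode = geometry_mode, true_pf = true_pf,
            seed = seed, noise_sd = noise_sd, state0 = state0,
            composition = composition)
}

series_volumes <- function(series) {
  mode <- attr(series, "geometry_mode") %||% "sphere"
  volumes_from_radii(series$R1_um, series$R2_um, series$r_um, mode)
}

#' Permeability from the initial shrinkage slope
#'
#' Estimates the osmotic water permeability from the initial rate of volume
#' change: a straight line is fit to the first `window` volume samples of
#' droplet 1 and the slope is divided by the initial driving force,
#' \deqn{P_f = \frac{dV_1/dt|_{t=0}}{V_w \, A_0 \, (c_1 - c_2)|_{t=0}}.}
#' The estimator is exact in the noiseless small-time limit; its bias grows
#' with the window length because the driving force decays along the fit
#' window.
#'
#' @param series A `shrinkage_series` (from [simulate_droplet_pair()],
#'   [gen_shrinkage()] or [read_shrinkage_series()]).
#' @param A0 Initial bilayer contact area (um^2); defaults to
#'   `pi * r_um[1]^2`.
#' @param window Number of leading samples used for the linear fit (>= 3).
#' @return A `pf_estimate` object; see [pf_fit_trajectory()].
#' @export
pf_initial_slope <- function(series, A0 = NULL, window = 5L) {
  if (nrow(series) < window || window < 3) {
    stop_domain("series must have at least `window` >= 3 samples")
  }
  dc0 <- osmolality_to_concentration(attr(series, "osmolality1")) -
    osmolality_to_concentration(attr(series, "osmolality2"))
  if (dc0 == 0) {
    stop_estimate("no osmotic driving force (equal osmolalities); Pf is unidentifiable")
  }
  A0 <- A0 %||% (pi * series$r_um[1]^2)
  V <- series_volumes(series)
  idx <- seq_len(window)
  fit <- lm(V$V1[idx] ~ series$t_s[idx])
  slope <- unname(coef(fit)[2])
  if (sign(slope) != sign(dc0) && abs(slope) > 0) {
    noise_sd <- attr(series, "noise_sd") %||% 0
    if (noise_sd == 0 || abs(slope) > 10 * noise_sd * mean(V$V1[idx])) {
      warn("early volume trend opposes the osmotic gradient; check the series")
    }
  }
  pf_hat <- slope / (.kv_flux * A0 * dc0)
  se <- tryCatch(
    abs(summary(fit)$coefficients[2, 2] / (.kv_flux * A0 * dc0)),
    error = function(e) NA_real_)
  new_pf_estimate(max(pf_hat, 0), method = "initial-slope", se = se,
                  residual_norm = sqrt(sum(stats::resid(fit)^2)),
                  n_points = window, series = series)
}

#' Permeability from a full-trajectory least-squares fit
#'
#' Fits the osmotic volume-flow model of [simulate_droplet_pair()] to an
#' observed shrinkage series by minimising the sum of squared radius
#' residuals over the permeability coefficient.  The standard error comes
#' from the local curvature of the least-squares objective,
#' `se = sqrt(2 sigma^2 / d2SS/dPf2)` with `sigma^2 = SS/(n - 1)`.
#'
#' @inheritParams pf_initial_slope
#' @param state0 Initial [droplet_pair_state()]; defaults to the one stored
#'   on a simulated series.
#' @param pf_max Upper bound of the search interval (um/s).
#' @return A `pf_estimate` object: a list with `pf_hat`, `method`, `se`,
#'   `residual_norm` and `n_points`, supporting [generics::tidy()] and
#'   [generics::glance()].
#' @export
pf_fit_trajectory <- function(series, state0 = NULL, pf_max = 500) {
  if (nrow(series) < 5) stop_domain("need at least 5 samples to fit")
  state0 <- state0 %||% attr(series, "state0")
  if (is.null(state0)) {
    stop_domain("state0 is required (none stored on the series)")
  }
  dc0 <- state0$n1 / state0$V1 - state0$n2 / state0$V2
  if (dc0 == 0) {
    stop_estimate("no osmotic driving force (equal concentrations); Pf is unidentifiable")
  }
  mode <- attr(series, "geometry_mode") %||% "sphere"
  t_end <- max(series$t_s)
  dt <- series$t_s[2] - series$t_s[1]
  obs <- c(series$R1_um, series$R2_um)

  ss <- function(pf) {
    pred <- simulate_droplet_pair(state0, pf, t_end = t_end, dt = dt,
                                  noise_sd = 0, geometry_mode = mode)
    pred <- pred[match(round(series$t_s, 9), round(pred$t_s, 9)), ]
    sum((c(pred$R1_um, pred$R2_um) - obs)^2)
  }
  opt <- optimize(ss, interval = c(0, pf_max), tol = 1e-5)
  pf_hat <- opt$minimum
  if (pf_hat > pf_max * (1 - 1e-3)) {
    abort("trajectory fit did not converge inside the search interval",
          class = "dibkit_cannot_estimate",
          data = list(best_pf = pf_hat, residual = sqrt(opt$objective)))
  }
  # curvature-based SE
  h <- max(1e-3, pf_hat * 1e-3)
  d2 <- (ss(pf_hat + h) - 2 * opt$objective + ss(max(pf_hat - h, 0))) / h^2
  n <- 2L * nrow(series)
  se <- if (is.finite(d2) && d2 > 0) {
    sqrt(2 * (opt$objective / (n - 1)) / d2)
  } else {
    NA_real_
  }
  new_pf_estimate(pf_hat, method = "trajectory-fit", se = se,
                  residual_norm = sqrt(opt$objective), n_points = nrow(series),
                  series = series)
}

new_pf_estimate <- function(pf_hat, method, se, residual_norm, n_points,
                            series = NULL) {
  structure(
    list(pf_hat = pf_hat, method = method, se = se,
         residual_norm = residual_norm, n_points = n_points,
         true_pf = attr(series, "true_pf")),
    class = "pf_estimate")
}

#' @export
print.pf_estimate <- function(x, ...) {
  cat(sprintf("Osmotic water permeability estimate (%s)\n", x$method))
  cat(sprintf("  Pf = %.3f um/s (SE %.3g), residual norm %.3g, n = %d\n",
              x$pf_hat, x$se, x$residual_norm, x$n_points))
  invisible(x)
}

#' Relative change in water permeability
#'
#' The percent change of a permeability relative to the matched drug-free
#' reference, `100 * (pf - pf0) / pf0`, rounded to the nearest whole percent
#' (the convention used when reporting relative permeability changes).
#'
#' @param pf Permeability with the perturbant present (um/s).
#' @param pf0 Reference permeability without the perturbant (um/s), positive.
#' @return Integer percent change. Vectorised.
#' @examples
#' relative_change(88, 71)  # 24
#' @export
relative_change <- function(pf, pf0) {
  if (any(!is.finite(pf0)) || any(pf0 <= 0)) {
    stop_domain("reference permeability pf0 must be positive")
  }
  as.integer(round(100 * (pf - pf0) / pf0))
}
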