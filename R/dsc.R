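#' Construct a thermogram record
#'
#' A temperature-scanned heat-flow trace together with the scan metadata
#' needed to normalise it to a molar excess heat capacity.
#'
#' @param T_C Temperature samples (degrees C), strictly increasing, at least
#'   20 points.
#' @param heat_flow_mW Endothermic heat flow (mW), endothermic-up sign
#'   convention.  Use `endothermic_down = TRUE` to flip traces recorded with
#'   the opposite convention.
#' @param scan_rate Scan rate (degrees C per minute), positive.
#' @param n_lipid Amount of lipid in the pan (mol), positive.
#' @param composition Optional label or list describing the membrane
#'   composition.
#' @param endothermic_down If `TRUE` the heat-flow trace is negated on input.
#' @return A `thermogram` tibble with columns `T_C` and `heat_flow_mW` and
#'   the scan metadata stored as attributes.
#' @export
thermogram <- function(T_C, heat_flow_mW, scan_rate, n_lipid,
                       composition = NULL, endothermic_down = FALSE) {
  if (length(T_C) < 20) stop_domain("a thermogram needs at least 20 samples")
  if (is.unsorted(T_C, strictly = TRUE)) {
    stop_domain("temperature axis must be strictly increasing")
  }
  if (scan_rate <= 0) stop_domain("scan_rate must be positive")
  if (n_lipid <= 0) stop_domain("n_lipid must be positive")
  if (endothermic_down) heat_flow_mW <- -heat_flow_mW
  structure(tibble(T_C = T_C, heat_flow_mW = heat_flow_mW),
            class = c("thermogram", class(tibble())),
            scan_rate = scan_rate, n_lipid = n_lipid,
            composition = composition)
}

# mW -> kcal/s, (C/min) -> (C/s)
.mw_to_kcal_s <- 1e-3 / 4184

#' Molar excess heat capacity from a heat-flow thermogram
#'
#' Normalises heat flow to a molar excess heat capacity on the same
#' temperature grid:
#' \deqn{C_p(T) = \frac{\dot q(T)}{\beta \, n_{lipid}}}
#' with the heat flow converted from mW to kcal/s and the scan rate
#' \eqn{\beta} from degrees C/min to degrees C/s.  The curve is linear in the
#' input: doubling `n_lipid` or the scan rate halves it.
#'
#' @param thermo A [thermogram()].
#' @return A `cp_curve` tibble with columns `T_C` and `cp_kcal_mol_C`.
#' @export
excess_heat_capacity <- function(thermo) {
  stopifnot(inherits(thermo, "thermogram"))
  scan_rate <- attr(thermo, "scan_rate")
  n_lipid <- attr(thermo, "n_lipid")
  cp <- (thermo$heat_flow_mW * .mw_to_kcal_s) / (scan_rate / 60) / n_lipid
  structure(tibble(T_C = thermo$T_C, cp_kcal_mol_C = cp),
            class = c("cp_curve", class(tibble())),
            composition = attr(thermo, "composition"))
}

window_idx <- function(T_C, window) {
  which(T_C >= window[1] & T_C <= window[2])
}

# most prominent sample of a curve, or NA if nothing rises above noise
detect_apex <- function(T_C, cp) {
  i <- which.max(cp)
  flank <- c(head(cp, max(3, length(cp) %/% 10)),
             tail(cp, max(3, length(cp) %/% 10)))
  noise <- stats::mad(flank, center = stats::median(flank))
  if (cp[i] <= stats::median(flank) + 5 * max(noise, 1e-12)) {
    return(NA_integer_)
  }
  i
}

#' Subtract a linear baseline from a heat-capacity curve
#'
#' Fits a straight line through the mean heat capacities of two flanking
#' temperature windows (one before, one after the transition) and subtracts
#' it.  Peak area is invariant to any linear ramp added to the input, and
#' the corrected curve averages approximately zero inside both windows.
#'
#' @param curve A `cp_curve` from [excess_heat_capacity()], or any data
#'   frame with columns `T_C` and `cp_kcal_mol_C`.
#' @param pre_window,post_window Length-2 numeric ranges (degrees C) flanking
#'   the transition; each must contain at least 3 samples and must not
#'   overlap a detected peak.
#' @return The corrected `cp_curve`, with the baseline coefficients
#'   (intercept, slope) stored in attribute `baseline`.
#' @export
subtract_baseline <- function(curve, pre_window, post_window) {
  T_C <- curve$T_C
  cp <- curve$cp_kcal_mol_C
  i_pre <- window_idx(T_C, pre_window)
  i_post <- window_idx(T_C, post_window)
  if (length(i_pre) < 3 || length(i_post) < 3) {
    stop_domain("each baseline window must contain at least 3 samples")
  }
  apex <- detect_apex(T_C, cp)
  if (!is.na(apex) && (apex %in% i_pre || apex %in% i_post)) {
    stop_domain("baseline window overlaps the transition peak")
  }
  x <- c(mean(T_C[i_pre]), mean(T_C[i_post]))
  y <- c(mean(cp[i_pre]), mean(cp[i_post]))
  slope <- (y[2] - y[1]) / (x[2] - x[1])
  intercept <- y[1] - slope * x[1]
  out <- tibble(T_C = T_C, cp_kcal_mol_C = cp - (intercept + slope * T_C))
  structure(out, class = c("cp_curve", class(tibble())),
            baseline = c(intercept = intercept, slope = slope),
            composition = attr(curve, "composition"))
}

#' Extract the main phase transition from a corrected heat-capacity curve
#'
#' Locates the dominant endothermic peak and reports the main transition
#' temperature `Tm` (the peak apex), the transition enthalpy `deltaH`
#' (trapezoidal integral over the peak support), and the full width at half
#' maximum.
#'
#' The apex is refined beyond the temperature grid by a parabolic fit over
#' the upper quartile of the peak (all samples at or above 75 percent of the
#' maximum), whose vertex is the reported `Tm`; for a symmetric peak this is
#' exact and decouples `Tm` precision from grid spacing.  The integration
#' support is the contiguous region around the apex where the corrected
#' curve exceeds `max(3 * noise, 1%% of apex)`, extended outward to the
#' baseline crossings.  If no sample rises above the noise floor a
#' no-transition result is returned (`deltaH = 0`, `Tm = NA`), the behaviour
#' expected of cholesterol-saturated membranes with no measurable
#' transition.
#'
#' @param curve A baseline-corrected `cp_curve` (see [subtract_baseline()]).
#' @return A `dsc_transition` object: list with `Tm`, `deltaH`, `fwhm`,
#'   `baseline`, and `found` (logical).  Supports [generics::tidy()].
#' @export
transition_params <- function(curve) {
  T_C <- curve$T_C
  cp <- curve$cp_kcal_mol_C
  apex <- detect_apex(T_C, cp)
  if (is.na(apex)) {
    return(new_dsc_transition(Tm = NA_real_, deltaH = 0, fwhm = NA_real_,
                              baseline = attr(curve, "baseline"),
                              found = FALSE,
                              composition = attr(curve, "composition")))
  }
  apex_cp <- cp[apex]
  flank_n <- max(3, length(cp) %/% 10)
  noise <- stats::mad(c(head(cp, flank_n), tail(cp, flank_n)))
  thr <- max(3 * noise, 0.01 * apex_cp)

  # contiguous supra-threshold region around the apex ...
  lo <- apex
  while (lo > 1 && cp[lo - 1] > thr) lo <- lo - 1
  hi <- apex
  while (hi < length(cp) && cp[hi + 1] > thr) hi <- hi + 1
  # ... extended to the baseline crossings
  while (lo > 1 && cp[lo - 1] > 0) lo <- lo - 1
  while (hi < length(cp) && cp[hi + 1] > 0) hi <- hi + 1

  deltaH <- trapz_integral(T_C[lo:hi], cp[lo:hi])

  # parabolic apex over the upper quartile of the peak
  top <- which(cp >= 0.75 * apex_cp & seq_along(cp) >= lo &
                 seq_along(cp) <= hi)
  Tm <- if (length(top) >= 3) {
    q <- lm(cp[top] ~ T_C[top] + I(T_C[top]^2))
    b <- coef(q)
    v <- -b[2] / (2 * b[3])
    if (is.finite(v) && v >= T_C[min(top)] && v <= T_C[max(top)]) {
      unname(v)
    } else {
      T_C[apex]
    }
  } else {
    T_C[apex]
  }

  half <- apex_cp / 2
  left <- cross_at(T_C, cp, seq(lo, apex), half)
  right <- cross_at(T_C, cp, seq(apex, hi), half)
  fwhm <- if (is.na(left) || is.na(right)) NA_real_ else right - left

  # flag multi-peak transitions: more than one sustained run above half max
  # (short noise-induced runs at the half-max crossings are ignored)
  runs <- rle(cp[lo:hi] > 0.5 * apex_cp)
  min_run <- max(5, (hi - lo) %/% 50)
  if (sum(runs$values & runs$lengths >= min_run) > 1) {
    warn("multiple comparable peaks inside the transition support")
  }

  new_dsc_transition(Tm = Tm, deltaH = max(deltaH, 0), fwhm = fwhm,
                     baseline = attr(curve, "baseline"), found = TRUE,
                     composition = attr(curve, "composition"))
}

# linear interpolation of the temperature where cp crosses `level`
cross_at <- function(T_C, cp, idx, level) {
  y <- cp[idx] - level
  s <- which(y[-1] * y[-length(y)] <= 0 & y[-1] != y[-length(y)])
  if (length(s) == 0) return(NA_real_)
  i <- idx[s[1]]
  T_C[i] + (T_C[i + 1] - T_C[i]) * (level - cp[i]) / (cp[i + 1] - cp[i])
}

new_dsc_transition <- function(Tm, deltaH, fwhm, baseline, found,
                               composition = NULL) {
  structure(list(Tm = Tm, deltaH = deltaH, fwhm = fwhm,
                 baseline = baseline, found = found,
                 composition = composition),
            class = "dsc_transition")
}

#' @export
print.dsc_transition <- function(x, ...) {
  if (!x$found) {
    cat("DSC transition: none detected (deltaH = 0)\n")
  } else {
    cat(sprintf("DSC transition: Tm = %.2f C, deltaH = %.2f kcal/mol, FWHM = %.2f C\n",
                x$Tm, x$deltaH, x$fwhm))
  }
  invisible(x)
}

#' Shift between two phase transitions
#'
#' Compares two extracted transitions and reports the transition-temperature
#' shift (`Tm_b - Tm_a`, rounded to one decimal) and the percent change of
#' the transition enthalpy (whole percents, the same rounding convention as
#' [relative_change()]).
#'
#' @param a,b `dsc_transition` objects (reference first).
#' @return A tibble with columns `delta_Tm_C` and `deltaH_change_pct`.
#' @examples
#' a <- structure(list(Tm = -17.58, deltaH = 9.59, found = TRUE),
#'                class = "dsc_transition")
#' b <- structure(list(Tm = -18.09, deltaH = 7.67, found = TRUE),
#'                class = "dsc_transition")
#' transition_shift(a, b)  # -0.5 C, -20 %
#' @export
transition_shift <- function(a, b) {
  stopifnot(inherits(a, "dsc_transition"), inherits(b, "dsc_transition"))
  if (!isTRUE(a$found) || !isTRUE(b$found) || is.na(a$Tm) || is.na(b$Tm)) {
    stop_domain("both transitions must have a defined Tm")
  }
  tibble(
    delta_Tm_C = round(b$Tm - a$Tm, 1),
    deltaH_change_pct = as.integer(round(100 * (b$deltaH - a$deltaH) / a$deltaH))
  )
}
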