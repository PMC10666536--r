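#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a permeability estimate
#'
#' @param x A `pf_estimate` from [pf_initial_slope()] or
#'   [pf_fit_trajectory()].
#' @param ... Unused.
#' @return A one-row tibble: `term`, `estimate`, `std.error`, `method`.
#' @exportS3Method generics::tidy
tidy.pf_estimate <- function(x, ...) {
  tibble(term = "pf_um_s", estimate = x$pf_hat, std.error = x$se,
         method = x$method)
}

#' Glance at a permeability estimate
#'
#' @inheritParams tidy.pf_estimate
#' @return A one-row tibble with fit diagnostics: `residual.norm`, `nobs`,
#'   `method`, and `true.pf` when the series carried ground truth.
#' @exportS3Method generics::glance
glance.pf_estimate <- function(x, ...) {
  tibble(residual.norm = x$residual_norm, nobs = x$n_points,
         method = x$method, true.pf = x$true_pf %||% NA_real_)
}

#' Tidy an extracted phase transition
#'
#' @param x A `dsc_transition` from [transition_params()].
#' @param ... Unused.
#' @return A one-row tibble: `Tm_C`, `deltaH_kcal_mol`, `fwhm_C`, `found`.
#' @exportS3Method generics::tidy
tidy.dsc_transition <- function(x, ...) {
  tibble(Tm_C = x$Tm, deltaH_kcal_mol = x$deltaH, fwhm_C = x$fwhm,
         found = x$found)
}

#' Glance at an extracted phase transition
#'
#' @inheritParams tidy.dsc_transition
#' @return A one-row tibble with the baseline coefficients and detection
#'   flag.
#' @exportS3Method generics::glance
glance.dsc_transition <- function(x, ...) {
  tibble(baseline.intercept = unname(x$baseline["intercept"]) %||% NA_real_,
         baseline.slope = unname(x$baseline["slope"]) %||% NA_real_,
         found = x$found)
}
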