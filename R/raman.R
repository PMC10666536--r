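#' Construct a Raman spectrum record
#'
#' @param wavenumber_cm1 Wavenumber axis (cm^-1), strictly increasing.
#' @param intensity Intensity (arbitrary units).
#' @param label Optional sample descriptor (composition, pH).
#' @return A `raman_spectrum` tibble with columns `wavenumber_cm1` and
#'   `intensity`.
#' @export
raman_spectrum <- function(wavenumber_cm1, intensity, label = NULL) {
  if (length(wavenumber_cm1) != length(intensity)) {
    stop_domain("wavenumber and intensity axes must have equal length")
  }
  if (is.unsorted(wavenumber_cm1, strictly = TRUE)) {
    stop_domain("wavenumber axis must be strictly increasing")
  }
  structure(tibble(wavenumber_cm1 = wavenumber_cm1, intensity = intensity),
            class = c("raman_spectrum", class(tibble())),
            label = label)
}

check_band_window <- function(spec, center, window) {
  rng <- range(spec$wavenumber_cm1)
  if (center - window < rng[1] || center + window > rng[2]) {
    stop_domain(sprintf(
      "band window %g +/- %g cm^-1 lies outside the spectral range [%g, %g]",
      center, window, rng[1], rng[2]))
  }
  invisible(TRUE)
}

#' Band intensity by windowed maximum
#'
#' Reads out the intensity of a band as the maximum intensity inside
#' `[center - window, center + window]`; the located position of that
#' maximum is reported alongside.  A windowed maximum is robust and
#' parameter-free compared to fitted band amplitudes.
#'
#' @param spec A `raman_spectrum` (or data frame with `wavenumber_cm1`,
#'   `intensity`).
#' @param center Nominal band centre (cm^-1).
#' @param window Half-width of the search window (cm^-1), default 10.
#' @return A one-row tibble: `center_nominal_cm1`, `position_cm1`,
#'   `intensity`.
#' @export
band_intensity <- function(spec, center, window = 10) {
  check_band_window(spec, center, window)
  idx <- which(spec$wavenumber_cm1 >= center - window &
                 spec$wavenumber_cm1 <= center + window)
  if (length(idx) == 0) stop_domain("band window contains no samples")
  i <- idx[which.max(spec$intensity[idx])]
  tibble(center_nominal_cm1 = center,
         position_cm1 = spec$wavenumber_cm1[i],
         intensity = spec$intensity[i])
}

#' Normalise a spectrum to the 2849 cm^-1 band
#'
#' Scales the whole spectrum so the maximum intensity inside the window
#' around `center` equals one.  This is the most intense phospholipid band
#' (methylene C-H symmetric stretch) and normalising to it permits relative
#' comparison across samples.  The operation is idempotent and invariant to
#' prior uniform scaling of the input.
#'
#' @inheritParams band_intensity
#' @param center Normalisation band centre, default 2849 cm^-1.
#' @param window Half-width of the band window (cm^-1), default 10.
#' @return The rescaled `raman_spectrum`.
#' @export
normalize_to_band <- function(spec, center = 2849, window = 10) {
  b <- band_intensity(spec, center, window)
  if (b$intensity <= 0) {
    stop_domain("normalisation band has non-positive intensity")
  }
  raman_spectrum(spec$wavenumber_cm1, spec$intensity / b$intensity,
                 label = attr(spec, "label"))
}

#' Subtract drug-originating bands by scaled reference subtraction
#'
#' Removes aspirin-originating bands from a mixed lipid+drug spectrum by
#' subtracting the pure-drug reference spectrum scaled to match the mixture
#' at an anchor band where the lipid does not scatter (by default the
#' 1606 cm^-1 aromatic C=C stretch of aspirin):
#' \deqn{k = I_{mix}(anchor) / I_{ref}(anchor), \qquad out = mix - k\,ref.}
#' A single-anchor scale is used deliberately: a full-spectrum least-squares
#' scale would be biased by the lipid bands.  The reference is resampled
#' onto the mixture's wavenumber grid by linear interpolation if the grids
#' differ.  Negative post-subtraction intensities are clipped to zero; the
#' clipped fraction is stored in attribute `clip_fraction` and a warning is
#' raised when it exceeds 5 percent (an over-subtraction indicator).
#'
#' @param mix Mixture `raman_spectrum`.
#' @param ref Pure-drug reference `raman_spectrum`.
#' @param anchor Anchor band centre (cm^-1), default 1606.
#' @param window Half-width of the anchor window (cm^-1), default 10.
#' @return The drug-subtracted `raman_spectrum`, with attributes `k_scale`
#'   and `clip_fraction`.
#' @export
subtract_asa_reference <- function(mix, ref, anchor = 1606, window = 10) {
  check_band_window(mix, anchor, window)
  check_band_window(ref, anchor, window)
  if (!isTRUE(all.equal(ref$wavenumber_cm1, mix$wavenumber_cm1))) {
    ref <- raman_spectrum(
      mix$wavenumber_cm1,
      stats::approx(ref$wavenumber_cm1, ref$intensity,
                    xout = mix$wavenumber_cm1, rule = 2)$y,
      label = attr(ref, "label"))
  }
  b_ref <- band_intensity(ref, anchor, window)
  noise_ref <- stats::mad(ref$intensity)
  if (b_ref$intensity <= max(3 * noise_ref, 0) || b_ref$intensity <= 0) {
    stop_domain("reference spectrum lacks a usable anchor band")
  }
  b_mix <- band_intensity(mix, anchor, window)
  k <- max(b_mix$intensity, 0) / b_ref$intensity
  if (k < 0) stop_domain("negative subtraction scale")
  out <- mix$intensity - k * ref$intensity
  clip_fraction <- mean(out < 0)
  out[out < 0] <- 0
  if (clip_fraction > 0.05) {
    warn(sprintf(
      "%.1f%% of points clipped at zero after subtraction (possible over-subtraction)",
      100 * clip_fraction))
  }
  res <- raman_spectrum(mix$wavenumber_cm1, out, label = attr(mix, "label"))
  attr(res, "k_scale") <- k
  attr(res, "clip_fraction") <- clip_fraction
  res
}

#' Acyl-chain order ratios from the C-H stretching region
#'
#' Computes the two intensity ratios used as acyl-chain order/disorder
#' indicators in phospholipid Raman spectra:
#' `I(2848)/I(2890)` (methylene symmetric over asymmetric C-H stretch,
#' sensitive to interchain coupling) and `I(2930)/I(2890)` (terminal methyl
#' over asymmetric stretch, sensitive to rotational disorder).  Increases in
#' either ratio indicate chain decoupling and disordering.  Band intensities
#' are windowed maxima ([band_intensity()]); when adjacent windows would
#' overlap they are partitioned at the midpoints between band centres.
#' For drug-containing mixtures, apply [subtract_asa_reference()] first.
#'
#' @param spec A `raman_spectrum` covering at least 2800--3000 cm^-1.
#' @param centers Nominal band centres (cm^-1): symmetric methylene,
#'   asymmetric methylene, terminal methyl.
#' @param window Half-width of each band window (cm^-1), default 10.
#' @return A one-row tibble: `r_sym_asym`, `r_term_asym`, and the located
#'   band positions `pos_sym_cm1`, `pos_asym_cm1`, `pos_term_cm1`.
#' @export
order_ratios <- function(spec, centers = c(sym = 2848, asym = 2890,
                                           term = 2930), window = 10) {
  centers <- sort(centers)
  # crowded bands: clamp windows at midpoints so partitions never overlap
  half_gaps <- diff(centers) / 2
  win <- pmin(window, c(half_gaps[1], min(half_gaps), half_gaps[2]))
  bands <- purrr::map2(centers, win, function(ctr, w) band_intensity(spec, ctr, w))
  names(bands) <- names(centers)
  # every band must rise clearly above the noise floor, judged against the
  # strongest C-H band and the overall spread of the trace
  apex <- max(purrr::map_dbl(bands, "intensity"))
  floor_lvl <- max(3 * stats::mad(spec$intensity, center = 0) * 1e-3,
                   1e-3 * apex)
  for (nm in names(bands)) {
    if (bands[[nm]]$intensity <= floor_lvl) {
      stop_domain(sprintf("band near %g cm^-1 is below the noise floor",
                          bands[[nm]]$center_nominal_cm1))
    }
  }
  tibble(
    r_sym_asym = bands$sym$intensity / bands$asym$intensity,
    r_term_asym = bands$term$intensity / bands$asym$intensity,
    pos_sym_cm1 = bands$sym$position_cm1,
    pos_asym_cm1 = bands$asym$position_cm1,
    pos_term_cm1 = bands$term$position_cm1
  )
}
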