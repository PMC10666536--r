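#' Default permeability response table
#'
#' True osmotic water permeability (um/s) for each membrane composition in
#' the synthetic study: POPC with and without cholesterol, with and without
#' aspirin (chi_asa = 0.5, the highest studied mole fraction), at pH 3
#' (uncharged drug) and pH 7 (charged drug).  The values encode the study
#' conditions the generators emulate: permeability rises with aspirin,
#' the rise is attenuated by cholesterol, and it is stronger at pH 3 than
#' at pH 7.
#'
#' @return A tibble with columns `lipid`, `chol_ratio`, `chi_asa`, `pH`,
#'   `pf_um_s`.
#' @export
default_pf_table <- function() {
  tibble::tribble(
    ~lipid, ~chol_ratio, ~chi_asa, ~pH, ~pf_um_s,
    "POPC", "none", 0.0, 3, 71,
    "POPC", "none", 0.5, 3, 88,
    "POPC", "none", 0.0, 7, 77,
    "POPC", "none", 0.5, 7, 85,
    "POPC", "10:1", 0.0, 3, 68,
    "POPC", "10:1", 0.5, 3, 77,
    "POPC", "10:1", 0.0, 7, 73,
    "POPC", "10:1", 0.5, 7, 75,
    "POPC", "4:1", 0.0, 3, 65,
    "POPC", "4:1", 0.5, 3, 70,
    "POPC", "1:1", 0.0, 3, 62,
    "POPC", "1:1", 0.5, 3, 63
  )
}

#' Default calorimetry response table
#'
#' Main-transition parameters (`Tm` in degrees C, `deltaH` in kcal/mol,
#' Gaussian peak width in degrees C) for DOPC multilamellar vesicles across
#' the synthetic study conditions: pure DOPC, DOPC with aspirin at 30:1 and
#' 3:1 lipid:drug mole ratios, and DOPC with cholesterol at 10:1, 4:1 and
#' 1:1 mole ratios (the last has no measurable transition).  Peak widths
#' increase with perturbation, mirroring the broadening of the endotherm.
#'
#' @return A tibble with columns `label`, `chol_ratio`, `asa_ratio`,
#'   `Tm_C`, `deltaH_kcal_mol`, `width_C`.
#' @export
default_dsc_table <- function() {
  tibble::tribble(
    ~label, ~chol_ratio, ~asa_ratio, ~Tm_C, ~deltaH_kcal_mol, ~width_C,
    "DOPC", "none", "none", -17.58, 9.59, 0.8,
    "DOPC:ASA 30:1", "none", "30:1", -18.09, 7.67, 1.0,
    "DOPC:ASA 3:1", "none", "3:1", -23.23, 1.33, 1.8,
    "DOPC:chol 10:1", "10:1", "none", -18.05, 6.14, 1.1,
    "DOPC:chol 4:1", "4:1", "none", -19.36, 3.18, 1.4,
    "DOPC:chol 1:1", "1:1", "none", NA_real_, 0, NA_real_
  )
}

default_raman_bands <- function() {
  list(
    # lipid bands: centre (cm^-1), amplitude (normalised units), sigma
    lipid = tibble::tribble(
      ~center, ~amplitude, ~sigma,
      1300, 0.40, 10,  # CH2 twist
      1440, 0.55, 9,   # CH2 bend
      1650, 0.35, 8,   # C=C stretch
      2848, 1.00, 9,   # CH2 symmetric stretch
      2890, 0.88, 11,  # CH2 asymmetric stretch
      2930, 0.45, 10   # terminal CH3 symmetric stretch
    ),
    asa = tibble::tribble(
      ~center, ~amplitude, ~sigma,
      1240, 0.30, 8,
      1606, 1.00, 6,   # aromatic C=C, the anchor band
      2940, 0.35, 9,
      3080, 0.25, 8
    ),
    # disorder response of the C-H bands: the symmetric stretch shifts up,
    # the asymmetric stretch loses intensity, the terminal stretch gains
    sym_shift_cm1 = 4,
    asym_loss = 0.32,
    term_gain = 0.25,
    # disorder per unit chi_asa; uncharged drug (pH 3) is the stronger
    # perturbant
    disorder_slope = c("3" = 1.0, "7" = 0.45),
    asa_scale = 1.6,
    # residual fluorescence background on lipid-containing spectra,
    # in units of the normalised 2848 peak
    background = 0.01
  )
}

#' Configuration of the synthetic study
#'
#' Bundles the seed, the per-modality noise scales, and the three response
#' tables that define the ground truth of every generated dataset.  All
#' generators are pure functions of this configuration and their seed:
#' identical inputs give identical outputs, and no generation is possible
#' without a seed.
#'
#' @param seed Integer master seed (mandatory).  Per-modality streams are
#'   derived from it by fixed offsets so each modality can be regenerated
#'   independently.
#' @param pf_response Permeability truth table; see [default_pf_table()].
#' @param dsc_response Calorimetry truth table; see [default_dsc_table()].
#' @param raman_bands Band parameter list; see the package vignette.
#' @param noise Named list of noise scales: `radius_rel` (relative, radii),
#'   `dsc_abs` (kcal mol^-1 C^-1, heat capacity), `raman_abs` (normalised
#'   intensity units).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed,
                         pf_response = default_pf_table(),
                         dsc_response = default_dsc_table(),
                         raman_bands = default_raman_bands(),
                         noise = list(radius_rel = 0.002, dsc_abs = 0.01,
                                      raman_abs = 0.002)) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop_domain("synth_config requires an integer seed")
  }
  structure(list(seed = as.integer(seed), pf_response = pf_response,
                 dsc_response = dsc_response, raman_bands = raman_bands,
                 noise = noise),
            class = "synth_config")
}

.seed_offset <- c(shrinkage = 101L, dsc = 211L, raman = 307L)

modality_seed <- function(config, modality, index = 0L) {
  (config$seed + .seed_offset[[modality]] + 13L * as.integer(index)) %% .Machine$integer.max
}

lookup_pf <- function(config, lipid, chol_ratio, chi_asa, pH) {
  row <- dplyr::filter(config$pf_response,
                       .data$lipid == !!lipid,
                       .data$chol_ratio == !!chol_ratio,
                       .data$chi_asa == !!chi_asa, .data$pH == !!pH)
  if (nrow(row) != 1) {
    stop_domain(sprintf("unknown composition: %s / chol %s / chi_asa %g / pH %s",
                        lipid, chol_ratio, chi_asa, pH))
  }
  row$pf_um_s
}

#' Generate a synthetic droplet shrinkage series
#'
#' Wraps [simulate_droplet_pair()] with the composition's true permeability
#' from the configuration's response table and the configured radius noise.
#' The true permeability is stored on the result (attribute `true_pf`) so
#' recovery tests always have ground truth.
#'
#' @param config A [synth_config()].
#' @param lipid,chol_ratio,chi_asa,pH Composition; must match a row of
#'   `config$pf_response`.
#' @param R0 Initial radius of both droplets (um).
#' @param r_contact Contact-zone radius (um).
#' @param osmolalities Length-2 initial osmolalities (mOsm/kg).
#' @param n_points Number of samples.
#' @param dt Sampling interval (s).
#' @param seed Seed; defaults to a stream derived from the master seed.
#' @param noise_sd Relative radius noise; defaults to the configured value.
#' @return A `shrinkage_series` (see [simulate_droplet_pair()]) with the
#'   composition attached.
#' @export
gen_shrinkage <- function(config, lipid = "POPC", chol_ratio = "none",
                          chi_asa = 0, pH = 3,
                          R0 = 150, r_contact = 60,
                          osmolalities = c(300, 100),
                          n_points = 60, dt = 30,
                          seed = modality_seed(config, "shrinkage"),
                          noise_sd = config$noise$radius_rel) {
  stopifnot(inherits(config, "synth_config"))
  pf <- lookup_pf(config, lipid, chol_ratio, chi_asa, pH)
  V0 <- 4 / 3 * pi * R0^3
  A <- pi * r_contact^2
  st <- droplet_pair_state(V0, V0, osmolalities[1], osmolalities[2], A)
  ser <- simulate_droplet_pair(st, pf, t_end = (n_points - 1) * dt, dt = dt,
                               noise_sd = noise_sd, seed = seed)
  attr(ser, "composition") <- list(lipid = lipid, chol_ratio = chol_ratio,
                                   chi_asa = chi_asa, pH = pH)
  ser
}

#' Generate a synthetic DSC thermogram
#'
#' Builds a Gaussian excess-heat-capacity transition with the configured
#' `(Tm, deltaH, width)` for the requested composition, adds a linear
#' instrumental baseline and Gaussian noise, and maps the curve back to a
#' heat-flow trace (the inverse of [excess_heat_capacity()]).  A zero
#' `deltaH` row produces a baseline-only trace with no transition.
#'
#' @param config A [synth_config()].
#' @param composition A `label` present in `config$dsc_response`.
#' @param grid Temperature grid (degrees C).
#' @param scan_rate Scan rate (degrees C/min).
#' @param n_lipid Amount of lipid (mol).
#' @param seed Seed; defaults to a stream derived from the master seed.
#' @param noise_sd Heat-capacity noise (kcal mol^-1 C^-1); defaults to the
#'   configured value.
#' @return A [thermogram()] with the truth parameters in attribute `truth`.
#' @export
gen_thermogram <- function(config, composition = "DOPC",
                           grid = seq(-40, 0, by = 0.02),
                           scan_rate = 5, n_lipid = 1e-5,
                           seed = modality_seed(config, "dsc"),
                           noise_sd = config$noise$dsc_abs) {
  stopifnot(inherits(config, "synth_config"))
  row <- dplyr::filter(config$dsc_response, .data$label == !!composition)
  if (nrow(row) != 1) {
    stop_domain(sprintf("unknown composition label '%s'", composition))
  }
  baseline <- 0.04 - 0.001 * grid
  cp <- baseline
  if (row$deltaH_kcal_mol > 0) {
    cp <- cp + row$deltaH_kcal_mol * dnorm(grid, row$Tm_C, row$width_C)
  }
  set.seed(seed)
  cp <- cp + rnorm(length(grid), 0, noise_sd)
  hf <- cp * (scan_rate / 60) * n_lipid / .mw_to_kcal_s
  th <- thermogram(grid, hf, scan_rate = scan_rate, n_lipid = n_lipid,
                   composition = composition)
  attr(th, "truth") <- list(Tm_C = row$Tm_C,
                            deltaH_kcal_mol = row$deltaH_kcal_mol,
                            width_C = row$width_C)
  th
}

gaussian_bands <- function(grid, bands) {
  Reduce(`+`, purrr::pmap(bands, function(center, amplitude, sigma) {
    amplitude * exp(-(grid - center)^2 / (2 * sigma^2))
  }), init = numeric(length(grid)))
}

lipid_bands_at_disorder <- function(raman_bands, disorder) {
  b <- raman_bands$lipid
  b$center[b$center == 2848] <- 2848 + raman_bands$sym_shift_cm1 * disorder
  b$amplitude[b$center == 2890] <-
    b$amplitude[b$center == 2890] * (1 - raman_bands$asym_loss * disorder)
  b$amplitude[b$center == 2930] <-
    b$amplitude[b$center == 2930] * (1 + raman_bands$term_gain * disorder)
  b
}

#' Generate synthetic Raman spectra for a lipid-drug mixture
#'
#' Produces three spectra on a common grid: the noisy mixture
#' (lipid bands at the disorder level implied by `chi_asa` and pH, plus
#' aspirin bands scaled by `chi_asa`, plus noise), the pure-drug reference,
#' and the noiseless pure-lipid truth spectrum that exact subtraction should
#' recover.  The disorder parameter grows linearly with `chi_asa`, with a
#' steeper slope for the pH-3 (uncharged drug) parameterisation than for
#' pH 7: it shifts the 2848 cm^-1 band upward, attenuates the 2890 cm^-1
#' band and strengthens the 2930 cm^-1 band, so both order ratios increase
#' with disorder.  The lipid truth has no band at the 1606 cm^-1 anchor by
#' construction.
#'
#' @param config A [synth_config()].
#' @param chi_asa Aspirin mole fraction in `[0, 0.5]`.
#' @param pH 3 or 7.
#' @param grid Wavenumber grid (cm^-1); must cover 1200--3100.
#' @param seed Seed; defaults to a stream derived from the master seed.
#' @param noise_sd Additive intensity noise; defaults to the configured
#'   value.
#' @return A list of `raman_spectrum` objects: `mixture`, `reference`,
#'   `lipid_truth`, plus the scalar `disorder` used.
#' @export
gen_raman <- function(config, chi_asa = 0, pH = 3,
                      grid = seq(1200, 3100, by = 0.5),
                      seed = modality_seed(config, "raman"),
                      noise_sd = config$noise$raman_abs) {
  stopifnot(inherits(config, "synth_config"))
  if (min(grid) > 1200 || max(grid) < 3100) {
    stop_domain("wavenumber grid must cover 1200-3100 cm^-1")
  }
  rb <- config$raman_bands
  slope <- rb$disorder_slope[[as.character(pH)]]
  if (is.null(slope)) stop_domain(sprintf("no disorder slope for pH %s", pH))
  disorder <- min(1, slope * chi_asa)

  bkg <- rb$background %||% 0
  lipid_int <- bkg + gaussian_bands(grid, lipid_bands_at_disorder(rb, disorder))
  asa_int <- gaussian_bands(grid, rb$asa)
  set.seed(seed)
  mix_int <- lipid_int + rb$asa_scale * chi_asa * asa_int +
    rnorm(length(grid), 0, noise_sd)
  mix_int[mix_int < 0] <- 0

  lab <- sprintf("POPC chi_asa=%.2f pH=%d", chi_asa, as.integer(pH))
  list(
    mixture = raman_spectrum(grid, mix_int, label = lab),
    reference = raman_spectrum(grid, asa_int, label = "ASA reference"),
    lipid_truth = raman_spectrum(grid, lipid_int,
                                 label = paste(lab, "(truth)")),
    disorder = disorder
  )
}

#' Generate a full synthetic study on disk
#'
#' Writes a directory of plain-text fixtures covering every condition of
#' the configured study — droplet shrinkage series for each permeability
#' condition, thermograms for each calorimetry condition, and Raman
#' mixture/reference/truth spectra over a grid of aspirin fractions at both
#' pH values — together with a `manifest.csv` mapping each file to its
#' composition and ground truth.  Generation is fully determined by the
#' configuration seed: the same configuration writes a byte-identical tree.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @param raman_chi Aspirin fractions for the Raman sweep.
#' @param n_rep Replicate droplet pairs per permeability condition; the
#'   reported permeability is their average, as in bench practice where
#'   each value averages many independent pairs.
#' @return The manifest tibble, invisibly; columns `file`, `modality`,
#'   `lipid`, `chol_ratio`, `chi_asa`, `pH`, `replicate`, `truth_pf_um_s`,
#'   `truth_Tm_C`, `truth_deltaH_kcal_mol`, `truth_disorder`.
#' @export
gen_study <- function(config, dir, raman_chi = c(0, 0.1, 0.25, 0.5),
                      n_rep = 8L) {
  stopifnot(inherits(config, "synth_config"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0) {
    stop_domain(sprintf("cannot write to destination '%s'", dir))
  }
  rows <- list()
  blank <- function() {
    tibble(file = NA_character_, modality = NA_character_,
           lipid = NA_character_, chol_ratio = NA_character_,
           chi_asa = NA_real_, pH = NA_real_, replicate = NA_integer_,
           truth_pf_um_s = NA_real_,
           truth_Tm_C = NA_real_, truth_deltaH_kcal_mol = NA_real_,
           truth_disorder = NA_real_)
  }

  for (i in seq_len(nrow(config$pf_response))) {
    cond <- config$pf_response[i, ]
    for (rep in seq_len(n_rep)) {
      ser <- gen_shrinkage(
        config, cond$lipid, cond$chol_ratio, cond$chi_asa, cond$pH,
        seed = modality_seed(config, "shrinkage", (i - 1L) * n_rep + rep))
      f <- sprintf("shrinkage_%02d_r%02d.csv", i, rep)
      write_shrinkage_series(ser, file.path(dir, f))
      row <- blank()
      row$file <- f; row$modality <- "shrinkage"
      row$lipid <- cond$lipid; row$chol_ratio <- cond$chol_ratio
      row$chi_asa <- cond$chi_asa; row$pH <- cond$pH
      row$replicate <- rep
      row$truth_pf_um_s <- cond$pf_um_s
      rows[[length(rows) + 1]] <- row
    }
  }

  for (i in seq_len(nrow(config$dsc_response))) {
    cond <- config$dsc_response[i, ]
    th <- gen_thermogram(config, cond$label,
                         seed = modality_seed(config, "dsc", i))
    f <- sprintf("thermogram_%02d.csv", i)
    write_thermogram(th, file.path(dir, f))
    row <- blank()
    row$file <- f; row$modality <- "dsc"
    row$lipid <- "DOPC"; row$chol_ratio <- cond$chol_ratio
    row$chi_asa <- NA_real_; row$pH <- 3
    row$truth_Tm_C <- cond$Tm_C
    row$truth_deltaH_kcal_mol <- cond$deltaH_kcal_mol
    rows[[length(rows) + 1]] <- row
  }

  ref_written <- FALSE
  k <- 0L
  for (pH in c(3, 7)) {
    for (chi in raman_chi) {
      k <- k + 1L
      sp <- gen_raman(config, chi_asa = chi, pH = pH,
                      seed = modality_seed(config, "raman", k))
      f <- sprintf("raman_mix_%02d.txt", k)
      write_spectrum(sp$mixture, file.path(dir, f))
      write_spectrum(sp$lipid_truth,
                     file.path(dir, sprintf("raman_truth_%02d.txt", k)))
      if (!ref_written) {
        write_spectrum(sp$reference, file.path(dir, "raman_asa_reference.txt"))
        ref_written <- TRUE
      }
      row <- blank()
      row$file <- f; row$modality <- "raman"
      row$lipid <- "POPC"; row$chol_ratio <- "none"
      row$chi_asa <- chi; row$pH <- pH
      row$truth_disorder <- sp$disorder
      rows[[length(rows) + 1]] <- row
    }
  }

  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Run the full analysis pipeline over a generated study directory
#'
#' Reads the manifest written by [gen_study()], analyses every fixture with
#' the package's estimators — trajectory permeability fits, baseline-
#' corrected transition extraction, and drug-subtracted order ratios — and
#' returns tidy per-modality result tables, including the relative
#' permeability change of each drug-containing condition against its
#' matched drug-free reference.
#'
#' @param dir A study directory produced by [gen_study()].
#' @param pre_window,post_window Baseline windows (degrees C) for the DSC
#'   branch.
#' @return A list of tibbles: `permeability` (with `pf_hat_um_s` and
#'   `change_pct`), `dsc` (`Tm_C`, `deltaH_kcal_mol`), `raman`
#'   (`r_sym_asym`, `r_term_asym`).
#' @export
study_report <- function(dir, pre_window = c(-40, -32),
                         post_window = c(-8, 0)) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE)

  shr <- dplyr::filter(manifest, .data$modality == "shrinkage")
  perm <- purrr::map_dfr(seq_len(nrow(shr)), function(i) {
    ser <- read_shrinkage_series(file.path(dir, shr$file[i]))
    fit <- pf_fit_trajectory(ser)
    dplyr::bind_cols(shr[i, c("lipid", "chol_ratio", "chi_asa", "pH")],
                     tibble(pf_fit_um_s = fit$pf_hat))
  })
  # each reported permeability averages the replicate droplet pairs
  perm <- perm |>
    dplyr::group_by(.data$lipid, .data$chol_ratio, .data$chi_asa, .data$pH) |>
    dplyr::summarise(pf_hat_um_s = mean(.data$pf_fit_um_s),
                     se_um_s = stats::sd(.data$pf_fit_um_s) /
                       sqrt(dplyr::n()),
                     n_pairs = dplyr::n(), .groups = "drop") |>
    dplyr::group_by(.data$lipid, .data$chol_ratio, .data$pH) |>
    dplyr::mutate(
      pf0 = .data$pf_hat_um_s[.data$chi_asa == 0][1],
      change_pct = relative_change(.data$pf_hat_um_s, .data$pf0)) |>
    dplyr::ungroup() |>
    dplyr::select(-"pf0")

  dsc <- dplyr::filter(manifest, .data$modality == "dsc")
  dsc_res <- purrr::map_dfr(seq_len(nrow(dsc)), function(i) {
    th <- read_thermogram(file.path(dir, dsc$file[i]))
    tr <- excess_heat_capacity(th) |>
      subtract_baseline(pre_window, post_window) |>
      transition_params()
    tibble(composition = attr(th, "composition") %||% dsc$file[i],
           chol_ratio = dsc$chol_ratio[i],
           Tm_C = tr$Tm, deltaH_kcal_mol = tr$deltaH, fwhm_C = tr$fwhm,
           found = tr$found)
  })

  ram <- dplyr::filter(manifest, .data$modality == "raman")
  ref <- read_spectrum(file.path(dir, "raman_asa_reference.txt"))
  ram_res <- purrr::map_dfr(seq_len(nrow(ram)), function(i) {
    sp <- read_spectrum(file.path(dir, ram$file[i]))
    if (ram$chi_asa[i] > 0) sp <- subtract_asa_reference(sp, ref)
    sp <- normalize_to_band(sp)
    dplyr::bind_cols(ram[i, c("chi_asa", "pH")], order_ratios(sp))
  })

  structure(list(permeability = perm, dsc = dsc_res, raman = ram_res),
            class = "dib_study_report")
}
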