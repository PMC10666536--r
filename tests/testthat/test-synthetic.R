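test_that("generators are pure functions of configuration and seed", {
  cfg <- synth_config(seed = 9)
  a <- gen_shrinkage(cfg, n_points = 15, dt = 30)
  b <- gen_shrinkage(cfg, n_points = 15, dt = 30)
  expect_identical(a$R1_um, b$R1_um)
  expect_identical(gen_thermogram(cfg)$heat_flow_mW,
                   gen_thermogram(cfg)$heat_flow_mW)
  expect_identical(gen_raman(cfg, 0.2, 3)$mixture$intensity,
                   gen_raman(cfg, 0.2, 3)$mixture$intensity)
  # a seed is mandatory
  expect_error(synth_config(), class = "dibkit_domain_error")
  # unknown compositions are rejected
  expect_error(gen_shrinkage(cfg, lipid = "DPPC"),
               class = "dibkit_domain_error")
  expect_error(gen_thermogram(cfg, "DOPC:ASA 7:1"),
               class = "dibkit_domain_error")
})

test_that("shrinkage generator stores truth and matches the deterministic core", {
  cfg <- noiseless_config()
  ser <- gen_shrinkage(cfg, "POPC", "none", 0.5, 3, n_points = 15, dt = 30)
  expect_equal(attr(ser, "true_pf"), 88)
  st <- attr(ser, "state0")
  direct <- simulate_droplet_pair(st, 88, t_end = 14 * 30, dt = 30)
  expect_equal(ser$R1_um, direct$R1_um)
})

test_that("thermogram generator closed loop recovers the configured truth", {
  cfg <- synth_config(seed = 3)
  for (comp in c("DOPC", "DOPC:chol 4:1")) {
    th <- gen_thermogram(cfg, comp)
    truth <- attr(th, "truth")
    tr <- th |>
      excess_heat_capacity() |>
      subtract_baseline(c(-40, -32), c(-8, 0)) |>
      transition_params()
    expect_equal(tr$Tm, truth$Tm_C, tolerance = 0.02 / abs(truth$Tm_C))
    expect_equal(tr$deltaH, truth$deltaH_kcal_mol, tolerance = 0.01)
  }
  # a zero-enthalpy composition produces no transition
  none <- gen_thermogram(cfg, "DOPC:chol 1:1") |>
    excess_heat_capacity() |>
    subtract_baseline(c(-40, -32), c(-8, 0)) |>
    transition_params()
  expect_false(none$found)
  expect_equal(none$deltaH, 0)
})

test_that("thermograms track the aspirin dose: lower Tm, smaller enthalpy", {
  cfg <- synth_config(seed = 4)
  labels <- c("DOPC", "DOPC:ASA 30:1", "DOPC:ASA 3:1")
  fits <- purrr::map(labels, function(l) {
    gen_thermogram(cfg, l) |>
      excess_heat_capacity() |>
      subtract_baseline(c(-40, -32), c(-8, 0)) |>
      transition_params()
  })
  tms <- purrr::map_dbl(fits, "Tm")
  dhs <- purrr::map_dbl(fits, "deltaH")
  expect_true(all(diff(tms) < 0))
  expect_true(all(diff(dhs) < 0))
})

test_that("raman generator: chi_asa = 0 mixture is the lipid truth plus noise", {
  cfg <- synth_config(seed = 6)
  sp <- gen_raman(cfg, chi_asa = 0, pH = 3)
  resid <- sp$mixture$intensity - sp$lipid_truth$intensity
  expect_lt(max(abs(resid)), 6 * cfg$noise$raman_abs)
  # the lipid truth has no anchor band
  expect_lt(band_intensity(sp$lipid_truth, 1606)$intensity, 0.02)
  # disorder grows faster with chi_asa at pH 3 than at pH 7
  expect_gt(gen_raman(cfg, 0.4, 3)$disorder, gen_raman(cfg, 0.4, 7)$disorder)
})

test_that("subtraction closed loop recovers truth ratios across the chi sweep", {
  cfg <- synth_config(seed = 8)
  for (chi in c(0.1, 0.3, 0.5)) {
    sp <- gen_raman(cfg, chi_asa = chi, pH = 3)
    got <- order_ratios(normalize_to_band(
      subtract_asa_reference(sp$mixture, sp$reference)))
    truth <- order_ratios(normalize_to_band(sp$lipid_truth))
    expect_equal(got$r_sym_asym, truth$r_sym_asym, tolerance = 0.01)
    expect_equal(got$r_term_asym, truth$r_term_asym, tolerance = 0.01)
  }
})

test_that("order ratios rise monotonically with disorder, steeper at pH 3", {
  cfg <- noiseless_config()
  chis <- c(0, 0.125, 0.25, 0.375, 0.5)
  ratios <- purrr::map_dfr(c(3, 7), function(ph) {
    purrr::map_dfr(chis, function(chi) {
      sp <- gen_raman(cfg, chi_asa = chi, pH = ph)
      s <- if (chi > 0) subtract_asa_reference(sp$mixture, sp$reference)
      else sp$mixture
      dplyr::mutate(order_ratios(normalize_to_band(s)), chi = chi, pH = ph)
    })
  })
  for (ph in c(3, 7)) {
    sub <- dplyr::filter(ratios, pH == ph)
    expect_true(all(diff(sub$r_sym_asym) > 0))
    expect_true(all(diff(sub$r_term_asym) > 0))
  }
  # per-unit-chi response is steeper for the uncharged (pH 3) drug
  slope <- function(ph, col) {
    sub <- dplyr::filter(ratios, pH == ph)
    (dplyr::last(sub[[col]]) - dplyr::first(sub[[col]])) / 0.5
  }
  expect_gt(slope(3, "r_sym_asym"), slope(7, "r_sym_asym"))
  expect_gt(slope(3, "r_term_asym"), slope(7, "r_term_asym"))
})

test_that("gen_study writes a reproducible manifest-backed fixture tree", {
  cfg <- synth_config(seed = 21)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- gen_study(cfg, d1, n_rep = 1L)
  m2 <- gen_study(synth_config(seed = 21), d2, n_rep = 1L)
  expect_gte(length(unique(m1$modality)), 3)
  expect_gte(nrow(m1), 24)
  # every fixture row carries its ground truth
  expect_true(all(!is.na(m1$truth_pf_um_s[m1$modality == "shrinkage"])))
  expect_true(all(!is.na(m1$truth_deltaH_kcal_mol[m1$modality == "dsc"])))
  expect_true(all(!is.na(m1$truth_disorder[m1$modality == "raman"])))
  # byte-identical regeneration under the same seed
  for (f in m1$file) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("end-to-end noiseless study reproduces the configured percent changes", {
  cfg <- noiseless_config()
  d <- withr::local_tempdir()
  gen_study(cfg, d, n_rep = 1L, raman_chi = c(0, 0.5))
  rep <- study_report(d)
  perm <- dplyr::arrange(rep$permeability, .data$chol_ratio, .data$pH,
                         .data$chi_asa)
  # recomputed percent changes equal those implied by the truth table
  truth <- default_pf_table() |>
    dplyr::group_by(.data$chol_ratio, .data$pH) |>
    dplyr::mutate(change = relative_change(.data$pf_um_s,
                                           .data$pf_um_s[.data$chi_asa == 0])) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chol_ratio, .data$pH, .data$chi_asa)
  expect_identical(perm$change_pct, truth$change)
  expect_setequal(perm$change_pct[perm$chi_asa == 0.5],
                  c(24L, 10L, 13L, 3L, 8L, 2L))
  # calorimetry truths are recovered on the same tree
  dsc <- rep$dsc[rep$dsc$found, ]
  expect_equal(dsc$deltaH_kcal_mol,
               c(9.59, 7.67, 1.33, 6.14, 3.18), tolerance = 0.01)
})

test_that("default study reproduces the qualitative effect orderings", {
  d <- withr::local_tempdir()
  gen_study(synth_config(seed = 31), d, raman_chi = c(0, 0.5))
  rep <- study_report(d)
  perm <- rep$permeability
  eff <- function(chol, ph) {
    with(perm, change_pct[chol_ratio == chol & pH == ph & chi_asa == 0.5])
  }
  # aspirin raises permeability for every composition at pH 3
  for (chol in c("none", "10:1", "4:1", "1:1")) expect_gt(eff(chol, 3), 0)
  # the effect shrinks as cholesterol increases
  expect_gt(eff("none", 3), eff("4:1", 3))
  expect_gt(eff("10:1", 3), eff("1:1", 3))
  # uncharged drug (pH 3) outpaces charged drug (pH 7) condition-wise
  expect_gte(eff("none", 3), eff("none", 7))
  expect_gte(eff("10:1", 3), eff("10:1", 7))
})
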