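test_that("osmolality maps to concentration under the dilute convention", {
  expect_equal(osmolality_to_concentration(0), 0)
  expect_equal(osmolality_to_concentration(200), 200)
  expect_equal(osmolality_to_concentration(c(1, 1000)), c(1, 1000))
  expect_error(osmolality_to_concentration(-1), class = "dibkit_domain_error")
})

test_that("volume reconstruction: sphere and truncated-cap modes", {
  v <- volumes_from_radii(100, 100, 0, mode = "sphere")
  expect_equal(v$V1, 4 / 3 * pi * 1e6)
  # vanishing cap: truncated equals sphere
  vt0 <- volumes_from_radii(100, 100, 0, mode = "truncated")
  expect_equal(vt0$V1, v$V1)
  # cap volume frozen against an independent evaluation of
  # pi h^2 (R - h/3) with h = 100 - sqrt(100^2 - 50^2) = 13.39746
  vt <- volumes_from_radii(100, 100, 50, mode = "truncated")
  expect_equal(v$V1 - vt$V1, 53870.82, tolerance = 1e-6)
  # truncated never exceeds the sphere
  for (r in c(10, 40, 80)) {
    vr <- volumes_from_radii(100, 90, r, mode = "truncated")
    expect_lt(vr$V1, v$V1)
    expect_lt(vr$V2, 4 / 3 * pi * 90^3)
  }
})

test_that("initial osmotic volume flux matches the hand-computed value", {
  # Pf = 70 um/s, A = 2000 um^2, delta osmolality = 200 mOsm/kg
  # => |dV1/dt| = 70e-6 * 18.05e-6 * 2e-9 * 200 m^3/s = 505.4 um^3/s
  V0 <- 1e7
  st <- droplet_pair_state(V0, V0, 300, 100, A = 2000)
  ser <- simulate_droplet_pair(st, pf = 70, t_end = 0.2, dt = 0.1)
  vol <- volumes_from_radii(ser$R1_um, ser$R2_um, ser$r_um, "sphere")
  slope <- (vol$V1[2] - vol$V1[1]) / 0.1
  expect_equal(slope, 505.4, tolerance = 1e-4)
})

test_that("simulated trajectories conserve volume and solutes and equilibrate", {
  st <- small_pair()
  ser <- simulate_droplet_pair(st, pf = 120, t_end = 20000, dt = 100)
  vol <- volumes_from_radii(ser$R1_um, ser$R2_um, ser$r_um, "sphere")
  vtot <- st$V1 + st$V2
  expect_true(all(abs(vol$V1 + vol$V2 - vtot) / vtot < 1e-9))
  # concentrations converge monotonically toward equality
  c1 <- st$n1 / vol$V1
  c2 <- st$n2 / vol$V2
  gap <- abs(c1 - c2)
  expect_true(all(diff(gap) < 1e-12))
  # closed-form equilibrium: V1/V2 -> n1/n2
  expect_equal(tail(vol$V1, 1) / tail(vol$V2, 1), st$n1 / st$n2,
               tolerance = 1e-3)
})

test_that("balanced osmolalities give a static droplet pair", {
  st <- small_pair(200, 200)
  ser <- simulate_droplet_pair(st, pf = 100, t_end = 1000, dt = 100)
  expect_equal(ser$R1_um, rep(ser$R1_um[1], nrow(ser)), tolerance = 1e-12)
  expect_equal(ser$R2_um, rep(ser$R2_um[1], nrow(ser)), tolerance = 1e-12)
})

test_that("noiseless simulation is deterministic; seeded noise reproduces", {
  st <- default_pair()
  a <- simulate_droplet_pair(st, 70, t_end = 300, dt = 30)
  b <- simulate_droplet_pair(st, 70, t_end = 300, dt = 30)
  expect_identical(a$R1_um, b$R1_um)
  n1 <- simulate_droplet_pair(st, 70, t_end = 300, dt = 30,
                              noise_sd = 0.01, seed = 11)
  n2 <- simulate_droplet_pair(st, 70, t_end = 300, dt = 30,
                              noise_sd = 0.01, seed = 11)
  n3 <- simulate_droplet_pair(st, 70, t_end = 300, dt = 30,
                              noise_sd = 0.01, seed = 12)
  expect_identical(n1$R1_um, n2$R1_um)
  expect_false(identical(n1$R1_um, n3$R1_um))
  expect_error(simulate_droplet_pair(st, 70, t_end = 300, dt = 30,
                                     noise_sd = 0.01),
               class = "dibkit_domain_error")
})

test_that("truncated geometry round-trips through forward and inverse paths", {
  st <- default_pair()
  ser <- simulate_droplet_pair(st, 70, t_end = 600, dt = 60,
                               geometry_mode = "truncated")
  vol <- volumes_from_radii(ser$R1_um, ser$R2_um, ser$r_um, "truncated")
  expect_equal(vol$V1[1], st$V1, tolerance = 1e-8)
  fit <- pf_fit_trajectory(ser)
  expect_equal(fit$pf_hat, 70, tolerance = 1e-3)
})

test_that("initial-slope estimator inverts the simulator at small times", {
  st <- default_pair()
  ser <- simulate_droplet_pair(st, 70, t_end = 45, dt = 1)
  est <- pf_initial_slope(ser, window = 5)
  expect_equal(est$pf_hat, 70, tolerance = 0.02)
  expect_s3_class(tidy(est), "tbl_df")
  # formula linearity: doubling the assumed area halves the estimate
  est2 <- pf_initial_slope(ser, A0 = 2 * pi * ser$r_um[1]^2, window = 5)
  expect_equal(est2$pf_hat, est$pf_hat / 2, tolerance = 1e-9)
  # zero driving force cannot be inverted
  ser0 <- simulate_droplet_pair(small_pair(200, 200), 70, t_end = 100, dt = 10)
  expect_error(pf_initial_slope(ser0), class = "dibkit_cannot_estimate")
})

test_that("initial-slope bias grows monotonically with the window length", {
  st <- default_pair()
  ser <- simulate_droplet_pair(st, 70, t_end = 1800, dt = 30)
  est <- vapply(c(5, 10, 20, 40, 60),
                function(w) pf_initial_slope(ser, window = w)$pf_hat,
                numeric(1))
  # the driving force decays along the window, so the estimate decays too
  expect_true(all(diff(est) < 0))
  expect_true(all(70 - est > 0))
})

test_that("trajectory fit recovers the generating permeability", {
  st <- default_pair()
  for (pf in c(30, 120)) {
    ser <- simulate_droplet_pair(st, pf, t_end = 1770, dt = 30)
    fit <- pf_fit_trajectory(ser)
    expect_equal(fit$pf_hat, pf, tolerance = 1e-3)
    expect_equal(glance(fit)$method, "trajectory-fit")
  }
  # small noisy study: mean over seeds stays close to the truth
  fits <- vapply(1:5, function(s) {
    ser <- simulate_droplet_pair(st, 70, t_end = 1770, dt = 30,
                                 noise_sd = 0.01, seed = s)
    pf_fit_trajectory(ser)$pf_hat
  }, numeric(1))
  expect_equal(mean(fits), 70, tolerance = 0.05)
  # unidentifiable when there is no gradient
  ser0 <- simulate_droplet_pair(small_pair(200, 200), 70, t_end = 300, dt = 30)
  expect_error(pf_fit_trajectory(ser0), class = "dibkit_cannot_estimate")
})

test_that("relative permeability change reproduces the printed whole percents", {
  expect_identical(relative_change(88, 71), 24L)
  expect_identical(relative_change(85, 77), 10L)
  expect_identical(relative_change(70, 65), 8L)
  expect_identical(relative_change(75, 73), 3L)
  expect_identical(relative_change(63, 62), 2L)
  expect_identical(relative_change(77, 77), 0L)
  expect_error(relative_change(70, 0), class = "dibkit_domain_error")
})
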