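test_that("DSS calibration shifts the reference maximum to exactly 0 ppm", {
  s <- toy_spectrum(peak_ppm = 0.02)
  cal <- calibrate(s)
  idx <- which(cal$ppm >= -0.2 & cal$ppm <= 0.2)
  expect_equal(cal$ppm[idx[which.max(cal$intensity[idx])]], 0,
               tolerance = 1e-9)
  expect_equal(attr(cal, "calibration_shift"), 0.02, tolerance = 1e-9)
  expect_identical(cal$intensity, s$intensity)

  # idempotent on an already-calibrated spectrum
  cal2 <- calibrate(cal)
  expect_equal(attr(cal2, "calibration_shift"), 0)
  expect_identical(cal2$ppm, cal$ppm)

  # flat spectrum has no reference peak
  flat <- spectrum1d(seq(11, -0.5, by = -0.01),
                     rep(0, length(seq(11, -0.5, by = -0.01))),
                     "S1", "M", "t1rho_short_a", 10)
  expect_error(calibrate(flat), "calibration failure")
})

test_that("calibration inverts a synthetic offset to within one grid step", {
  nu <- nuisance_model(noise_sd = 0, shift_offset_sd = 0.01,
                       protein_baseline_amplitude = 0, seed = 21)
  st <- tiny_study(kd = Inf, nuisance = nu)
  for (sp in list(st$measurements$M_mix1$short_a,
                  st$measurements$M_mix1$long)) {
    cal <- calibrate(sp)
    idx <- which(cal$ppm >= 2.9 & cal$ppm <= 3.1)
    peak_at <- cal$ppm[idx[which.max(cal$intensity[idx])]]
    expect_lt(abs(peak_at - 3.0), 0.002 + 1e-12)
  }
})

test_that("summing short replicates is point-wise and checks its contract", {
  a <- toy_spectrum(peak_height = 1)
  b <- toy_spectrum(peak_height = 0.9)
  s <- sum_short_replicates(a, b)
  expect_equal(max(s$intensity), 1.9)
  expect_equal(sum_short_replicates(a, a)$intensity, 2 * a$intensity)
  shifted <- a; shifted$ppm <- a$ppm + 0.01
  expect_error(sum_short_replicates(a, shifted), "axis mismatch")
  l <- toy_spectrum(experiment = "t1rho_long", spin_lock_ms = 200)
  expect_error(sum_short_replicates(a, l), "10 ms")
})

test_that("the stability metric is the symmetric relative difference", {
  w <- c(-0.05, 0.05)
  a <- toy_spectrum(peak_height = 1.00)
  expect_identical(stability_reldiff(a, a, w), 0)
  b <- toy_spectrum(peak_height = 0.94)
  expect_equal(stability_reldiff(a, b, w), 0.06 / 0.97, tolerance = 1e-12)
  expect_gt(stability_reldiff(a, b, w), 0.05)   # unstable side
  c <- toy_spectrum(peak_height = 0.97)
  expect_equal(stability_reldiff(a, c, w), 0.03 / 0.985, tolerance = 1e-12)
  expect_lt(stability_reldiff(a, c, w), 0.05)   # stable side
  expect_error(stability_reldiff(a, b, c(20, 21)), "outside")
})

test_that("the gain check flags only marked negative values", {
  expect_identical(gain_check(1.0, 1.0, 0), 0)
  expect_equal(gain_check(1.0, 1.28, 0.2), -0.08)  # flagged territory
  expect_equal(gain_check(1.0, 1.23, 0.2), -0.03)  # below-threshold gain
  th <- screen_thresholds()
  expect_true(gain_check(1.0, 1.28, 0.2) < th$gain_min)
  expect_false(gain_check(1.0, 1.23, 0.2) < th$gain_min)
})

test_that("noise estimation recovers a known generator sd", {
  ppm <- seq(11, -0.5, by = -0.002)
  set.seed(31)
  est <- replicate(20, {
    y <- rnorm(length(ppm), 0, 0.01) + 0.001 * ppm  # noise on a sloped base
    s <- spectrum1d(ppm, y, "S1", "M", "t1rho_short_a", 10)
    estimate_noise(s, c(10.5, 11.0))
  })
  expect_true(all(abs(est - 0.01) / 0.01 < 0.3))
  zero <- spectrum1d(ppm, rep(0, length(ppm)), "S1", "M", "t1rho_short_a", 10)
  expect_identical(estimate_noise(zero, c(10.5, 11.0)), 0)
  expect_error(estimate_noise(zero, c(11.19, 11.2)), "10 grid points")
  expect_error(estimate_noise(zero, c(20, 21)), "outside")
})

test_that("peak quantification fills intensities, S/N and flags", {
  th <- screen_thresholds()
  # noiseless null study: no residual signal, peak unquantifiable
  st0 <- tiny_study(kd = Inf)
  q0 <- quantify_peak(st0$measurements$M_mix1, st0$measurements$P_prot01,
                      st0$measurements$PM_prot01_mix1, c(2.975, 3.025), th)
  expect_equal(q0$snr, 0)
  expect_match(q0$flags, "low_snr")

  # strong synthetic binder at modest noise clears every gate
  nu <- nuisance_model(noise_sd = 0.005, seed = 13)
  st1 <- tiny_study(kd = 50, nuisance = nu)
  q1 <- quantify_peak(st1$measurements$M_mix1, st1$measurements$P_prot01,
                      st1$measurements$PM_prot01_mix1, c(2.975, 3.025), th)
  expect_gt(q1$snr, 2)
  expect_identical(q1$flags, "")
  expect_equal(q1$i_m_short, 1)

  # 10% loss between the short replicates trips the stability filter
  nu2 <- nuisance_model(noise_sd = 0, shift_offset_sd = 0,
                        degradation_rates = c(met01 = 0.0527),
                        protein_baseline_amplitude = 0, seed = 1)
  st2 <- tiny_study(kd = 50, nuisance = nu2)
  q2 <- quantify_peak(st2$measurements$M_mix1, st2$measurements$P_prot01,
                      st2$measurements$PM_prot01_mix1, c(2.975, 3.025), th)
  expect_gt(q2$stability_reldiff, 0.05)
  expect_match(q2$flags, "unstable")

  # missing / misassigned role is refused
  expect_error(quantify_peak(st0$measurements$P_prot01,
                             st0$measurements$P_prot01,
                             st0$measurements$PM_prot01_mix1,
                             c(2.975, 3.025), th), "role")
})

test_that("filters are order-independent functions of the stored numbers", {
  nu <- nuisance_model(noise_sd = 0.01, seed = 17)
  st <- tiny_study(kd = 100, nuisance = nu)
  th <- screen_thresholds()
  q <- quantify_peak(st$measurements$M_mix1, st$measurements$P_prot01,
                     st$measurements$PM_prot01_mix1, c(2.975, 3.025), th)
  flags <- character()
  if (q$stability_reldiff > th$stability_max) flags <- c(flags, "unstable")
  if (q$gain_value < th$gain_min) flags <- c(flags, "gained")
  if (!(q$snr > th$snr_min)) flags <- c(flags, "low_snr")
  expect_identical(q$flags, paste(flags, collapse = ";"))
})

test_that("mixed long delays between M and PM are refused", {
  r <- tiny_rosters()
  st_small <- generate_study(data.frame(protein_id = "prot01", small = TRUE),
                             r$peak_lists, r$mix, binding_truth(),
                             nuisance = null_nuisance())
  st_big <- tiny_study(kd = Inf)
  expect_error(quantify_peak(st_big$measurements$M_mix1,
                             st_small$measurements$P_prot01,
                             st_small$measurements$PM_prot01_mix1,
                             c(2.975, 3.025)),
               "delays differ")
})
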