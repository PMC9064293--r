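test_that("plate formula evaluates the printed relation", {
  # F = 0.5 uN, R1 = 250 um, R2 = 80 um, R3 = 150 um, A = 60 deg
  sig <- plate_sigma(0.5e-6, 250e-6, 80e-6, 150e-6, 60 * pi / 180)
  expect_equal(sig, 1.428137e-3, tolerance = 1e-6)
  # linear in F
  expect_equal(plate_sigma(1e-6, 250e-6, 80e-6, 150e-6, 60 * pi / 180),
               2 * sig, tolerance = 1e-12)
})

test_that("plate formula round-trips synthesized geometries to machine precision", {
  set.seed(42)
  for (i in 1:20) {
    sig <- stats::runif(1, 0.5e-3, 5e-3)
    R1 <- stats::runif(1, 100e-6, 400e-6)
    R2 <- stats::runif(1, 50e-6, 200e-6)
    R3 <- stats::runif(1, 50e-6, 200e-6)
    A <- stats::runif(1, 0.3, 2.5)
    denom <- pi * R3^2 * (1 / R1 + 1 / R2) - 2 * pi * R3 * sin(A)
    if (denom <= 0) next
    f <- sig * denom
    expect_equal(plate_sigma(f, R1, R2, R3, A), sig, tolerance = 1e-14)
  }
})

test_that("degenerate contact geometry raises a geometry error", {
  r <- 150e-6
  expect_error(plate_sigma(0.5e-6, r, r, r, pi / 2), "geometry")
  expect_error(plate_sigma(0.5e-6, -1, 80e-6, 150e-6, 1), "radii")
  expect_error(plate_sigma(0.5e-6, 250e-6, 80e-6, 150e-6, 4), "contact angle")
})

test_that("sigma carries units: scaling all lengths scales sigma inversely", {
  f <- 0.5e-6; R1 <- 250e-6; R2 <- 80e-6; R3 <- 150e-6; A <- 1
  s1 <- plate_sigma(f, R1, R2, R3, A)
  s2 <- plate_sigma(f, 1e3 * R1, 1e3 * R2, 1e3 * R3, A)
  expect_equal(s2, s1 / 1e3, tolerance = 1e-12)
})

test_that("strain computation flags the protocol band", {
  s <- compute_strain(100e-6, 80e-6)
  expect_equal(s$strain, 0.20)
  expect_equal(s$regime, "in_protocol")
  expect_equal(compute_strain(1, 1)$strain, 0)
  # above 22% strain the response is solid-like (tension readings jump)
  expect_equal(compute_strain(100e-6, 75e-6)$regime, "solid_like_regime")
  expect_equal(compute_strain(100e-6, 90e-6)$regime, "below_protocol")
  expect_error(compute_strain(80e-6, 100e-6), "h > h0")
})

test_that("noise-free push-back traces decompose exactly", {
  tr <- synth_pushback_trace(noise_sd = 0, onset_time = 3600, ramp_rate = 5e-9)
  pb <- analyze_pushback(tr)
  expect_equal(pb$onset_time, 3600, tolerance = 1)   # within one sample
  expect_equal(pb$delta_F_30min, 5e-9 * 1800, tolerance = 1e-4)
  expect_equal(pb$plateau_force, 1.5e-7, tolerance = 1e-3)
})

test_that("ramp-free traces yield no onset", {
  for (s in 1:5) {
    tr <- synth_pushback_trace(ramp_rate = 0, seed = s)
    pb <- analyze_pushback(tr)
    expect_true(is.na(pb$onset_time))
    expect_true("no_onset" %in% pb$flags)
    expect_true(is.na(pb$delta_F_30min))
  }
})

test_that("onset detection is invariant to a constant force offset", {
  tr <- synth_pushback_trace(seed = 9)
  pb0 <- analyze_pushback(tr)
  tr2 <- force_trace(tr$t, tr$force + 5e-7)
  pb2 <- analyze_pushback(tr2)
  expect_equal(pb2$onset_time, pb0$onset_time, tolerance = 1.5)
  expect_equal(pb2$plateau_force - pb0$plateau_force, 5e-7, tolerance = 1e-9)
})

test_that("onset recovery at instrument-scale noise", {
  errs <- vapply(1:20, function(s) {
    pb <- analyze_pushback(synth_pushback_trace(seed = s))
    pb$onset_time - 3600
  }, numeric(1))
  expect_gte(mean(abs(errs) <= 300), 0.9)
})

test_that("short traces are refused", {
  tr <- synth_pushback_trace(duration = 300)
  expect_error(analyze_pushback(tr), "too short")
})

test_that("30-min force gain is reported from both reference points", {
  tr <- synth_pushback_trace(noise_sd = 0, onset_time = 2000, ramp_rate = 2e-10,
                             duration = 5400)
  pb <- analyze_pushback(tr)
  expect_equal(pb$delta_F_30min, 2e-10 * 1800, tolerance = 1e-3)
  expect_true(is.finite(pb$delta_F_30min_from_start))
})
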