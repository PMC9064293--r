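test_that("noise-free synthetic contours lie on the oracle profile", {
  cont <- synth_drop_contour(GAMMA_REF, DRHO_REF, R0_REF, radial_noise_sd = 0)
  ctx <- fluid_context(GAMMA_REF, DRHO_REF)
  p <- integrate_profile(ctx, R0_REF, theta_stop = 2.7, n_out = 3000)
  d <- tensiomorph:::polyline_min_dist(abs(cont$x), cont$z, p$x, p$z)
  expect_lt(max(d) / R0_REF, 1e-5)
})

test_that("zero-Bond contours are circles of radius R0", {
  cont <- synth_drop_contour(GAMMA_REF, delta_rho = 0, R0_REF)
  r <- sqrt(cont$x^2 + (cont$z - R0_REF)^2)
  expect_lt(max(abs(r - R0_REF)), 1e-6 * R0_REF)
})

test_that("generators are deterministic per seed and leave the RNG stream alone", {
  a <- synth_drop_contour(GAMMA_REF, DRHO_REF, R0_REF, radial_noise_sd = 0.02, seed = 7)
  b <- synth_drop_contour(GAMMA_REF, DRHO_REF, R0_REF, radial_noise_sd = 0.02, seed = 7)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  t1 <- synth_pushback_trace(seed = 11)
  t2 <- synth_pushback_trace(seed = 11)
  expect_identical(serialize(t1, NULL), serialize(t2, NULL))
  k1 <- synth_track_table(seed = 5)
  k2 <- synth_track_table(seed = 5)
  expect_identical(serialize(k1, NULL), serialize(k2, NULL))
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(synth_drop_contour(GAMMA_REF, DRHO_REF, R0_REF, seed = 3))
  expect_identical(rnorm(1), before)
})

test_that("contour noise scales linearly with the requested SD", {
  ctx <- fluid_context(GAMMA_REF, DRHO_REF)
  p <- integrate_profile(ctx, R0_REF, theta_stop = 2.7, n_out = 3000)
  sd_at <- function(noise, seeds = 1:50) {
    devs <- vapply(seeds, function(s) {
      cont <- synth_drop_contour(GAMMA_REF, DRHO_REF, R0_REF,
                                 radial_noise_sd = noise, seed = s)
      stats::sd(tensiomorph:::polyline_min_dist(abs(cont$x), cont$z, p$x, p$z))
    }, numeric(1))
    mean(devs)
  }
  ratio <- sd_at(0.02) / sd_at(0.01)
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("generator truth is carried in metadata", {
  cont <- synth_drop_contour(GAMMA_REF, DRHO_REF, R0_REF, seed = 1)
  tr <- attr(cont, "truth")
  expect_equal(tr$gamma, GAMMA_REF)
  expect_equal(tr$bond, DRHO_REF * G_STD * R0_REF^2 / GAMMA_REF)
  trace <- synth_pushback_trace(seed = 1)
  expect_equal(attr(trace, "truth")$onset_time, 3600)
  tracks <- synth_track_table(seed = 1)
  expect_equal(attr(tracks, "truth")$initial_width, 1e-3)
})

test_that("generator specs are validated", {
  expect_error(synth_drop_contour(-1, DRHO_REF, R0_REF), "gamma")
  expect_error(synth_drop_contour(GAMMA_REF, DRHO_REF, R0_REF, n_points = 10),
               "n_points")
  expect_error(synth_drop_contour(GAMMA_REF, DRHO_REF, R0_REF,
                                  radial_noise_sd = -0.1), "radial_noise_sd")
  expect_error(synth_pushback_trace(dt = 0), "dt")
  expect_error(synth_drop_image(GAMMA_REF, DRHO_REF, R0 = 0, pixel_scale = 1e-6),
               "blank frame")
})

test_that("noise-free push-back traces have the constructed shape", {
  tr <- synth_pushback_trace(noise_sd = 0, onset_time = 3600, ramp_rate = 5e-9,
                             preload = 2.5e-7, relax_amplitude = 1e-7,
                             relax_tau = 60)
  # F(0) = preload (+ plateau_level = 0)
  expect_equal(tr$force[1], 2.5e-7, tolerance = 1e-12)
  # after relaxation, before onset: asymptote preload - relax_amplitude
  i <- tr$t > 2000 & tr$t < 3600
  expect_equal(max(abs(tr$force[i] - 1.5e-7)), 0, tolerance = 1e-9)
  # first strictly increasing sample after relaxation is at the onset
  d <- diff(tr$force)
  rising <- which(d > 1e-12 & tr$t[-1] > 1000)
  expect_equal(tr$t[rising[1] + 1], 3601)
  # ramp slope equals ramp_rate
  j <- tr$t >= 3700
  expect_equal(unname(diff(range(tr$force[j])) / diff(range(tr$t[j]))), 5e-9,
               tolerance = 1e-6)
})

test_that("ramp-free traces carry no onset in their truth", {
  tr <- synth_pushback_trace(ramp_rate = 0, seed = 2)
  expect_true(is.na(attr(tr, "truth")$onset_time))
})

test_that("track tables follow the piecewise-linear width construction", {
  reg <- data.frame(label = "R1", rate_before = 10, rate_after = 10,
                    changepoint = NA)
  tk <- synth_track_table(reg, t_start = 0, t_end = 2, dt = 0.1,
                          positional_noise_sd = 0)
  rs <- region_widths(tk)
  expect_equal(rs$ratio[rs$t == 2], 0.8, tolerance = 1e-12)
  # zero rate: constant separation
  reg0 <- data.frame(label = "R0", rate_before = 0, rate_after = 0,
                     changepoint = NA)
  tk0 <- synth_track_table(reg0, t_start = 0, t_end = 2, dt = 0.1,
                           positional_noise_sd = 0)
  expect_equal(unique(region_widths(tk0)$ratio), 1)
})

test_that("over-convergence is rejected", {
  reg <- data.frame(label = "bad", rate_before = 60, rate_after = 60,
                    changepoint = NA)
  expect_error(synth_track_table(reg, t_start = 0, t_end = 2, dt = 0.1),
               "over-convergence")
})

test_that("synthetic outputs serialize as CSV with YAML truth sidecars", {
  dir <- withr::local_tempdir()
  cont <- synth_drop_contour(GAMMA_REF, DRHO_REF, R0_REF, seed = 4)
  f <- file.path(dir, "cont.csv")
  write_contour_csv(cont, f)
  expect_true(file.exists(paste0(f, ".yaml")))
  back <- read_contour_csv(f)
  expect_equal(back$x, cont$x, tolerance = 1e-12)
  expect_equal(yaml::read_yaml(paste0(f, ".yaml"))$gamma, GAMMA_REF)
  tr <- synth_pushback_trace(seed = 4)
  ft <- file.path(dir, "trace.csv")
  write_trace_csv(tr, ft)
  expect_equal(read_trace_csv(ft)$force, tr$force, tolerance = 1e-12)
  tk <- synth_track_table(seed = 4)
  fk <- file.path(dir, "tracks.csv")
  write_tracks_csv(tk, fk)
  expect_equal(read_tracks_csv(fk)$x, tk$x, tolerance = 1e-12)
})

test_that("rendered drop silhouettes match the analytic area", {
  img <- synth_drop_image(GAMMA_REF, DRHO_REF, R0_REF, pixel_scale = 7.5e-6,
                          blur_sd = 0, noise_sd = 0)
  tr <- attr(img, "truth")
  poly <- tr$contour_px
  a_analytic <- abs(pracma::polyarea(poly[, 1], poly[, 2]))
  a_mask <- sum(img$data > 0.5)
  expect_lt(abs(a_mask - a_analytic), nrow(img$data))  # within one pixel row
})
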