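test_that("zero-gravity limit is a sphere and the apex is umbilic", {
  ctx <- fluid_context(GAMMA_REF, delta_rho = 0)
  p <- integrate_profile(ctx, R0_REF)
  expect_equal(attr(p, "bond"), 0)
  # circular arc: every point at distance R0 from the center (0, R0)
  r <- sqrt(p$x^2 + (p$z - R0_REF)^2)
  expect_lt(max(abs(r - R0_REF)) / R0_REF, 1e-8)
  expect_equal(equatorial_radius(p) / R0_REF, 1, tolerance = 1e-8)
  # umbilic apex and constant curvature everywhere
  expect_equal(p$R1[1], R0_REF)
  expect_equal(p$R2[1], R0_REF)
  expect_lt(max(abs(p$R1 - R0_REF)) / R0_REF, 1e-4)
  expect_lt(max(abs(p$R2 - R0_REF)) / R0_REF, 1e-4)
})

test_that("apex condition: dtheta/ds tends to 1/R0", {
  for (Bo in c(0.3, 1, 4)) {
    ctx <- fluid_context(GAMMA_REF, drho_for_bond(Bo))
    p <- integrate_profile(ctx, R0_REF)
    s1 <- p$s[2]
    expect_equal(p$theta[2] / s1, 1 / R0_REF, tolerance = 1e-6)
  }
})

test_that("Young-Laplace equation holds pointwise along converged profiles", {
  for (Bo in c(0.1, 1, 5)) {
    ctx <- fluid_context(GAMMA_REF, drho_for_bond(Bo))
    p <- integrate_profile(ctx, R0_REF, n_out = 4000)
    expect_lt(max(laplace_residual(p)), 1e-6)
  }
})

test_that("profiles are scale-equivariant and Bond-invariant under (R0, c) scaling", {
  k <- 3.7
  ctx1 <- fluid_context(GAMMA_REF, DRHO_REF)
  ctx2 <- fluid_context(GAMMA_REF * k^2, DRHO_REF)  # c -> c / k^2
  p1 <- integrate_profile(ctx1, R0_REF, n_out = 500)
  p2 <- integrate_profile(ctx2, R0_REF * k, n_out = 500)
  expect_equal(attr(p1, "bond"), attr(p2, "bond"), tolerance = 1e-12)
  # compare at common tangent angles via interpolation
  th <- seq(0.1, min(max(p1$theta), max(p2$theta)) - 0.05, length.out = 40)
  x1 <- stats::spline(p1$theta[-1], p1$x[-1], xout = th)$y
  x2 <- stats::spline(p2$theta[-1], p2$x[-1], xout = th)$y
  expect_equal(x2, k * x1, tolerance = 1e-6)
})

test_that("gravity flattening is monotone in Bond number", {
  # at fixed apex radius, increasing Bo strictly shrinks the equatorial
  # radius relative to R0 while the width/height aspect strictly grows
  bos <- c(0, 0.5, 1, 2, 5)
  eq <- asp <- numeric(length(bos))
  for (i in seq_along(bos)) {
    ctx <- fluid_context(GAMMA_REF, drho_for_bond(bos[i]))
    p <- integrate_profile(ctx, R0_REF, theta_stop = pi / 2, n_out = 800)
    eq[i] <- equatorial_radius(p) / R0_REF
    asp[i] <- equatorial_radius(p) / max(p$z)
  }
  expect_true(all(diff(eq) < 0))
  expect_true(all(diff(asp) > 0))
})

test_that("integration rejects invalid inputs", {
  ctx <- fluid_context(GAMMA_REF, DRHO_REF)
  expect_error(integrate_profile(ctx, R0 = -1), "R0")
  expect_error(integrate_profile(ctx, R0_REF, s_max = 0), "s_max")
  expect_error(fluid_context(-1, 40), "gamma")
  expect_error(fluid_context(GAMMA_REF, -5), "delta_rho")
})

test_that("capillary constant is consistent with its constituents", {
  ctx <- fluid_context(GAMMA_REF, DRHO_REF, G_STD)
  expect_equal(ctx$capillary_constant, DRHO_REF * G_STD / GAMMA_REF,
               tolerance = 1e-12)
})

test_that("profile CSV export round-trips the sampled columns", {
  ctx <- fluid_context(GAMMA_REF, DRHO_REF)
  p <- integrate_profile(ctx, R0_REF, n_out = 50)
  f <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(p, f)
  back <- read.csv(f)
  expect_equal(back$x, p$x, tolerance = 1e-12)
  expect_equal(back$theta, p$theta, tolerance = 1e-12)
})
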