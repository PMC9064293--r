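test_that("widths and ratios follow the point-pair construction", {
  # static points: ratio identically 1
  tk <- synth_track_table(data.frame(label = "S", rate_before = 0,
                                     rate_after = 0, changepoint = NA),
                          positional_noise_sd = 0)
  rs <- region_widths(tk)
  expect_equal(unique(rs$ratio), 1)
  expect_equal(rs$ratio[1], 1)  # first ratio 1 by construction
  # translation invariance
  tk2 <- synth_track_table(seed = 1)
  shifted <- tk2
  shifted$x <- shifted$x + 0.01
  shifted$y <- shifted$y - 0.02
  shifted <- track_table(shifted, pairs = attr(tk2, "pairs"))
  expect_equal(region_widths(shifted)$ratio, region_widths(tk2)$ratio,
               tolerance = 1e-12)
  # uniform rescaling invariance
  scaled <- tk2
  scaled$x <- scaled$x * 1e3
  scaled$y <- scaled$y * 1e3
  scaled <- track_table(scaled, pairs = attr(tk2, "pairs"))
  expect_equal(region_widths(scaled)$ratio, region_widths(tk2)$ratio,
               tolerance = 1e-12)
})

test_that("rates are exact on noise-free linear ratio series", {
  rs <- region_series(seq(0, 2, by = 0.1), seq(1, 0.8, length.out = 21))
  r <- estimate_rate(rs)
  expect_equal(r$rate, 10, tolerance = 1e-10)
  # constant series: zero rate
  rs0 <- region_series(seq(0, 2, by = 0.1), rep(5e-4, 21))
  expect_equal(estimate_rate(rs0)$rate, 0, tolerance = 1e-12)
  expect_error(estimate_rate(region_series(c(0, 1), c(1, 0.9))), ">= 3")
})

test_that("noisy rate estimates recover generator truth", {
  reg <- data.frame(label = "N7", rate_before = 7, rate_after = 7,
                    changepoint = NA)
  rates <- vapply(1:20, function(s) {
    rs <- region_widths(synth_track_table(reg, seed = s))
    estimate_rate(rs)$rate
  }, numeric(1))
  expect_lt(abs(mean(rates) - 7), 0.5)
})

test_that("changepoint detection recovers the two-regime construction", {
  tk <- synth_track_table(positional_noise_sd = 0)
  rs <- region_widths(tk)
  cp <- detect_rate_change(rs, region = "NIMZ")
  expect_true(cp$has_changepoint)
  expect_equal(cp$changepoint, -0.7, tolerance = 1e-8)  # exact at a sample
  expect_equal(cp$rate_before, 7, tolerance = 1e-6)
  expect_equal(cp$rate_after, 0, tolerance = 1e-6)
  # pure single-slope series: no changepoint
  expect_false(detect_rate_change(rs, region = "IMZ")$has_changepoint)
})

test_that("post-breakpoint IMZ-NIMZ rate difference reproduces the regime split", {
  diffs <- vapply(1:10, function(s) {
    rs <- region_widths(synth_track_table(seed = s))
    after <- c(-0.7, 2)
    estimate_rate(rs, window = after, region = "IMZ")$rate -
      estimate_rate(rs, window = after, region = "NIMZ")$rate
  }, numeric(1))
  expect_true(all(diffs > 4))
})

test_that("spherical correction matches closed forms and is monotone", {
  R <- 0.6e-3
  # full hemisphere: true/projected exactly 2
  expect_equal(spherical_cap_area(R, R)$factor, 2, tolerance = 1e-12)
  # flat limit
  expect_equal(spherical_cap_area(R, R * sin(0.009))$factor, 1, tolerance = 1e-3)
  # r = R/2: 2(1 - cos 30 deg) / (1/2)^2
  expect_equal(spherical_cap_area(R, R / 2)$factor,
               2 * (1 - cos(pi / 6)) / 0.25, tolerance = 1e-12)
  f <- spherical_cap_area(R, seq(0.05, 1, by = 0.05) * R)$factor
  expect_true(all(diff(f) > 0))
  expect_error(spherical_cap_area(R, 1.1 * R), "exceeds")
  # annulus = difference of caps
  expect_equal(spherical_annulus_area(R, 0, R),
               spherical_cap_area(R, R)$area_true, tolerance = 1e-12)
})

test_that("blastopore closure ratios behave like areas", {
  t <- 0:10
  r0 <- 0.3e-3 * (1 - t / 12)           # shrinking blastopore radius
  A_bp <- pi * r0^2
  A_we <- rep(pi * (0.7e-3)^2, 11)
  cc <- blastopore_closure(t, A_bp, A_we)
  expect_equal(cc$ratio, A_bp / A_we, tolerance = 1e-12)
  # closed when area is zero
  expect_equal(blastopore_closure(0, 0, 1)$ratio, 0)
  # invariant under a uniform pixel-scale change
  cc2 <- blastopore_closure(t, A_bp * 4, A_we * 4)
  expect_equal(cc2$ratio, cc$ratio, tolerance = 1e-12)
  # radius halving drops the ratio 4-fold
  r1 <- blastopore_closure(0:1, pi * c(1, 0.25) * 1e-8, rep(1e-6, 2))
  expect_equal(r1$ratio[1] / r1$ratio[2], 4, tolerance = 1e-12)
  expect_error(blastopore_closure(0, 2, 1), "exceeds")
})

test_that("cell shape metrics match closed forms for circles and ellipses", {
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  circ <- data.frame(cell = "c", t = 0, x = 10 * cos(th), y = 10 * sin(th))
  m <- cell_shape_metrics(circ)
  expect_equal(m$circularity, 1, tolerance = 1e-3)
  expect_equal(m$length_width_ratio, 1, tolerance = 1e-3)
  # 2:1 ellipse: LWR 2, circularity ~ 0.84 (Ramanujan perimeter)
  ell <- data.frame(cell = "e", t = 0, x = 20 * cos(th), y = 10 * sin(th))
  me <- cell_shape_metrics(ell)
  expect_equal(me$length_width_ratio, 2, tolerance = 1e-3)
  expect_equal(me$circularity, 0.8412, tolerance = 1e-3)
})

test_that("stationary cells have zero centroid speed", {
  th <- seq(0, 2 * pi, length.out = 61)[-61]
  two <- rbind(data.frame(cell = "c", t = 0, x = cos(th), y = sin(th)),
               data.frame(cell = "c", t = 2.5, x = cos(th), y = sin(th)))
  m <- cell_shape_metrics(two)
  expect_equal(m$centroid_speed[2], 0, tolerance = 1e-12)
  expect_equal(m$perimeter_change[2], 0, tolerance = 1e-12)
})

test_that("self-intersecting cell outlines are rejected with a message", {
  tpar <- seq(0, 2 * pi, length.out = 41)[-41]
  bow <- data.frame(cell = "b", t = 0, x = sin(2 * tpar), y = sin(tpar))
  expect_message(out <- cell_shape_metrics(bow), "self-intersecting")
  expect_null(out)
})

test_that("group summaries use mean, SEM and the pooled unpaired t test", {
  # identical values: SEM zero
  gs <- summarize_groups(c(2, 2, 2, 5, 5, 5), rep(c("a", "b"), each = 3))
  expect_equal(gs$summary$sem, c(0, 0))
  # identical groups: t = 0, p = 1
  gs2 <- summarize_groups(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(gs2$t, 0)
  expect_equal(gs2$p_value, 1)
  # reference-implementation oracle
  x <- c(9.7, 10.3, 11.2, 10.8, 9.9)
  y <- c(6.8, 7.4, 7.1, 6.5)
  gs3 <- summarize_groups(c(x, y), rep(c("x", "y"), c(5, 4)))
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(gs3$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(gs3$p_value, ref$p.value, tolerance = 1e-10)
  gs4 <- summarize_groups(c(x, y), rep(c("x", "y"), c(5, 4)), welch = TRUE)
  refw <- stats::t.test(x, y)
  expect_equal(gs4$t, unname(refw$statistic), tolerance = 1e-10)
  expect_equal(gs4$p_value, refw$p.value, tolerance = 1e-10)
  expect_equal(gs3$summary$sem[1], stats::sd(x) / sqrt(5), tolerance = 1e-12)
  # n = 1 group: SEM undefined, flagged
  gs5 <- summarize_groups(c(1, 2, 3), c("a", "a", "b"))
  expect_true(is.na(gs5$summary$sem[2]))
  expect_true("sem_undefined_for_n_lt_2" %in% gs5$flags)
})

test_that("unmatched timepoints are omitted with a log message", {
  tk <- synth_track_table(seed = 1)
  df <- as.data.frame(tk)
  df <- df[!(df$point_id == "IMZ_L" & df$t == df$t[3]), ]
  tk2 <- track_table(df, pairs = attr(tk, "pairs"))
  expect_message(rs <- region_widths(tk2), "omitted")
  expect_equal(sum(rs$region == "IMZ"), length(unique(tk$t)) - 1)
})
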