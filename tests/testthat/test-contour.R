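test_that("max projection is the elementwise maximum over slices", {
  a <- matrix(c(1, 3, 5, 2), 2, 2)
  b <- matrix(c(4, 1, 0, 6), 2, 2)
  st <- image_stack(array(c(a, b) / 10, dim = c(2, 2, 2)), 1e-6)
  expect_equal(max_project(st)$data, matrix(c(4, 3, 5, 6) / 10, 2, 2))
  # single-slice stack projects to itself
  st1 <- image_stack(array(a / 10, dim = c(2, 2, 1)), 1e-6)
  expect_equal(max_project(st1)$data, a / 10)
  # 2-D input returned unchanged (with a note)
  st2 <- image_stack(a / 10, 1e-6)
  expect_message(out <- max_project(st2), "2-D")
  expect_identical(out$data, st2$data)
})

test_that("a blurred disk extracts to the analytic circle", {
  img <- disk_image(r = 50, blur = 2)
  cont <- extract_contour(img)
  # closed silhouette area within 3% of pi r^2 (in physical units)
  a <- abs(pracma::polyarea(cont$x, cont$z)) / img$pixel_scale^2
  expect_lt(abs(a - pi * 50^2) / (pi * 50^2), 0.03)
  qc <- attr(cont, "qc")
  expect_gt(qc$circularity, 0.95)
  expect_true(qc$accepted)
})

test_that("extraction fails on blank images", {
  blank <- image_stack(matrix(0, 64, 64), 1e-6)
  expect_error(extract_contour(blank), "extraction failed")
})

test_that("star-shaped silhouettes are rejected by convexity deficiency", {
  n <- 200
  th <- seq(0, 2 * pi, length.out = 721)
  r <- 50 * (1 + 0.45 * cos(5 * th))
  gx <- rep(seq_len(n) - 0.5, times = n)
  gz <- rep(seq_len(n) - 0.5, each = n)
  inside <- mgcv::in.out(cbind(n / 2 + r * cos(th), n / 2 + r * sin(th)),
                         cbind(gx, gz))
  img <- image_stack(EBImage::gblur(matrix(as.numeric(inside), n, n), 2), 1e-6)
  cont <- extract_contour(img)
  qc <- attr(cont, "qc")
  expect_gt(qc$convexity_deficiency, 0.15)
  expect_false(qc$accepted)
})

test_that("QC metrics match closed forms for circles and ellipses", {
  th <- seq(0, 2 * pi, length.out = 401)[-401]
  circ <- observed_contour(data.frame(x = cos(th), z = 2 + sin(th)),
                           closed = TRUE)
  q <- qc_contour(circ)
  expect_equal(q$circularity, 1, tolerance = 1e-3)
  expect_lte(q$circularity, 1)
  expect_true(q$accepted)
  # 2:1 ellipse: circularity 4*pi*A/P^2 with Ramanujan perimeter ~ 0.8412
  ell <- observed_contour(data.frame(x = 2 * cos(th), z = 2 + sin(th)),
                          closed = TRUE)
  a <- 2; b <- 1; h <- ((a - b) / (a + b))^2
  P_ram <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  expect_equal(qc_contour(ell)$circularity, 4 * pi * (pi * a * b) / P_ram^2,
               tolerance = 1e-3)
})

test_that("self-intersecting outlines fail QC", {
  # figure-eight style bowtie, padded to the 20-point minimum
  tpar <- seq(0, 2 * pi, length.out = 41)[-41]
  x <- sin(2 * tpar); z <- sin(tpar)
  bow <- observed_contour(data.frame(x = x, z = z + 2), closed = TRUE)
  q <- qc_contour(bow)
  expect_false(q$simple)
  expect_false(q$accepted)
})

test_that("QC metrics are scale invariant", {
  cont <- synth_drop_contour(GAMMA_REF, DRHO_REF, R0_REF,
                             radial_noise_sd = 0.01, seed = 3)
  q1 <- qc_contour(cont)
  scaled <- observed_contour(data.frame(x = cont$x * 1e3, z = cont$z * 1e3),
                             closed = TRUE)
  q2 <- qc_contour(scaled)
  expect_equal(q1$circularity, q2$circularity, tolerance = 1e-10)
  expect_equal(q1$convexity_deficiency, q2$convexity_deficiency, tolerance = 1e-10)
})

test_that("confocal stacks are projected before extraction", {
  img <- disk_image(r = 40, n = 128, blur = 2)
  half1 <- img$data; half1[, 1:64] <- 0
  half2 <- img$data; half2[, 65:128] <- 0
  st <- image_stack(array(c(half1, half2), dim = c(128, 128, 2)), 1e-6,
                    slice_spacing = 1e-5)
  cont <- extract_contour(st)
  a <- abs(pracma::polyarea(cont$x, cont$z)) / 1e-12
  expect_lt(abs(a - pi * 40^2) / (pi * 40^2), 0.05)
})
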