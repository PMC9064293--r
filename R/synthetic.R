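# Synthetic-data generators. No raw movies or force traces were deposited for
# the measurements this package models, so every downstream estimator is
# exercised by parameter recovery on generated inputs that carry their ground
# truth in metadata.

#' Construct an observed aggregate contour
#'
#' An ordered 2-D outline of a tissue aggregate in physical units (meters),
#' apex-up with `z` increasing downward, as produced by contour extraction or
#' by the synthetic generator.
#'
#' @param points data frame (or matrix) with columns `x`, `z` in meters.
#' @param pixel_scale meters per pixel of the source image (`NA` if the
#'   contour was not image-derived).
#' @param source optional metadata list (stage, time relative to gastrulation
#'   onset, tissue label, provenance flags).
#' @param truth optional ground-truth list attached by generators.
#' @param closed is the outline a closed polygon? Default `FALSE` (a sessile
#'   profile truncated at the substrate).
#' @return Object of class `observed_contour`.
#' @export
observed_contour <- function(points, pixel_scale = NA_real_, source = list(),
                             truth = NULL, closed = FALSE) {
  points <- as.data.frame(points)
  if (!all(c("x", "z") %in% names(points)))
    stop_validation("contour points need columns 'x' and 'z'")
  points <- points[, c("x", "z")]
  if (nrow(points) < 20)
    stop_validation("a contour needs at least 20 points (got %d)", nrow(points))
  if (!all(is.finite(points$x)) || !all(is.finite(points$z)))
    stop_validation("contour coordinates must be finite")
  if (!is.na(pixel_scale) && pixel_scale <= 0)
    stop_validation("'pixel_scale' must be > 0 (m/pixel)")
  structure(points,
            pixel_scale = pixel_scale, source = source, truth = truth,
            closed = closed, qc = NULL,
            class = c("observed_contour", "data.frame"))
}

#' @export
print.observed_contour <- function(x, ...) {
  tr <- attr(x, "truth")
  cat(sprintf("Observed contour: %d points, x range [%.3g, %.3g] m, z range [0, %.3g] m\n",
              nrow(x), min(x$x), max(x$x), max(x$z)))
  if (!is.null(tr))
    cat(sprintf("  synthetic truth: gamma = %.4g mN/m, R0 = %.4g m, Bo = %.4g\n",
                1e3 * tr$gamma, tr$R0, tr$bond))
  qc <- attr(x, "qc")
  if (!is.null(qc)) cat(sprintf("  QC: %s\n", if (qc$accepted) "accepted" else "rejected"))
  invisible(x)
}

# Noise-free drop outline for (gamma, delta_rho, R0): both halves of the
# profile ordered left base -> apex -> right base. Returns x, z, theta and the
# outward normal at each point.
drop_outline <- function(gamma, delta_rho, R0, g, n_points, theta_max) {
  if (delta_rho == 0) {
    s_end <- R0 * theta_max
    u <- seq(-s_end, s_end, length.out = n_points)
    th <- abs(u) / R0
    sgn <- sign(u); sgn[sgn == 0] <- 1
    x <- sgn * R0 * sin(th); z <- R0 * (1 - cos(th))
  } else {
    ctx <- fluid_context(gamma, delta_rho, g)
    p <- integrate_profile(ctx, R0, theta_stop = theta_max, n_out = 1200)
    s_end <- max(p$s)
    u <- seq(-s_end, s_end, length.out = n_points)
    xs <- stats::splinefun(p$s, p$x, method = "natural")
    zs <- stats::splinefun(p$s, p$z, method = "natural")
    ts <- stats::splinefun(p$s, p$theta, method = "natural")
    th <- ts(abs(u)); th[abs(u) < 1e-300] <- 0
    sgn <- sign(u); sgn[sgn == 0] <- 1
    x <- sgn * xs(abs(u)); z <- zs(abs(u))
  }
  # outward normal: (sin th, -cos th) on the right half, mirrored on the left
  list(x = x, z = z, theta = th,
       nx = sgn * sin(th), nz = -cos(th))
}

#' Generate a synthetic drop-profile contour with known tension
#'
#' Samples `n_points` along the noise-free Young-Laplace outline for
#' `(gamma, delta_rho, R0)`, perturbs each point along the local outward
#' normal by `N(0, radial_noise_sd * R0)` so that the noise level is directly
#' interpretable as contour roughness, and optionally rotates the outline
#' about the apex by `tilt`. The generating parameters (including the Bond
#' number) are recorded in the `truth` attribute; downstream recovery tests
#' read truth from there only.
#'
#' @param gamma tension (N/m), > 0.
#' @param delta_rho density difference (kg/m^3), >= 0; 0 gives a circular arc
#'   of radius `R0` (the zero-Bond sphere limit).
#' @param R0 apex radius (m), > 0.
#' @param n_points number of contour points (>= 20).
#' @param radial_noise_sd noise SD as a fraction of `R0`.
#' @param tilt rotation about the apex (rad).
#' @param seed integer seed; identical seeds give identical contours.
#' @param g gravitational acceleration (m/s^2).
#' @param theta_max tangent angle at which the outline is truncated (rad);
#'   default 2.6 (~149 deg), a sessile aggregate with high contact angle.
#' @return An [observed_contour()].
#' @examples
#' cont <- synth_drop_contour(0.22e-3, 40, 7.5e-4, seed = 1)
#' attr(cont, "truth")$bond
#' @export
synth_drop_contour <- function(gamma, delta_rho, R0, n_points = 200,
                               radial_noise_sd = 0, tilt = 0, seed = NULL,
                               g = 9.80665, theta_max = 2.6) {
  if (!is.numeric(gamma) || gamma <= 0) stop_validation("'gamma' must be > 0")
  if (!is.numeric(delta_rho) || delta_rho < 0) stop_validation("'delta_rho' must be >= 0")
  if (!is.numeric(R0) || R0 <= 0) stop_validation("'R0' must be > 0")
  if (n_points < 20) stop_validation("'n_points' must be >= 20")
  if (radial_noise_sd < 0) stop_validation("'radial_noise_sd' must be >= 0")
  out <- drop_outline(gamma, delta_rho, R0, g, n_points, theta_max)
  eps <- with_seed(seed, stats::rnorm(n_points, 0, radial_noise_sd * R0))
  x <- out$x + eps * out$nx
  z <- out$z + eps * out$nz
  if (tilt != 0) {
    xr <- x * cos(tilt) - z * sin(tilt)
    zr <- x * sin(tilt) + z * cos(tilt)
    x <- xr; z <- zr
  }
  observed_contour(data.frame(x = x, z = z),
                   truth = list(gamma = gamma, delta_rho = delta_rho, R0 = R0,
                                g = g, bond = delta_rho * g * R0^2 / gamma,
                                tilt = tilt, radial_noise_sd = radial_noise_sd,
                                theta_max = theta_max, seed = seed),
                   source = list(kind = "synthetic_drop"), closed = TRUE)
}

#' Image stack container
#'
#' A 2-D image or small confocal stack. The intensity array is indexed
#' `[ix, iz(, slice)]` with the first index horizontal and the second the
#' vertical (depth) axis increasing downward from the top of the frame;
#' pixel `(ix, iz)` has its center at physical `((ix - 0.5), (iz - 0.5)) *
#' pixel_scale`.
#'
#' @param data 2-D matrix or 3-D array of intensities in `[0, 1]`.
#' @param pixel_scale meters per pixel, > 0.
#' @param slice_spacing slice spacing (m) for confocal stacks (the source
#'   protocol used 10 um intervals); `NA` for single images.
#' @param channel label.
#' @return Object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_scale, slice_spacing = NA_real_,
                        channel = "unknown") {
  if (length(data) == 0) stop_validation("image stack must be non-empty")
  if (!is.numeric(pixel_scale) || pixel_scale <= 0)
    stop_validation("'pixel_scale' must be > 0 (m/pixel)")
  d <- length(dim(data))
  if (!d %in% c(2L, 3L)) stop_validation("image data must be 2-D or 3-D")
  structure(list(data = data, pixel_scale = pixel_scale,
                 slice_spacing = slice_spacing, channel = channel),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Image stack: %s px, pixel scale %.3g m/px, channel '%s'\n",
              paste(d, collapse = " x "), x$pixel_scale, x$channel))
  invisible(x)
}

#' Render a synthetic drop image
#'
#' Rasterizes the filled silhouette of a Young-Laplace drop (closed at the
#' substrate chord) into a binary mask, Gaussian-blurs it, and adds pixel
#' noise, producing a fixture for the contour-extraction pipeline. The
#' noise-free generating contour (in pixel coordinates) is stored in the
#' `truth` attribute.
#'
#' @inheritParams synth_drop_contour
#' @param pixel_scale meters per pixel, > 0.
#' @param blur_sd Gaussian blur SD in pixels.
#' @param noise_sd additive pixel-intensity noise SD (intensities in `[0, 1]`).
#' @param margin frame margin as a fraction of the drop extent.
#' @param width,height optional frame size in pixels; an error is raised if
#'   the drop does not fit.
#' @return An [image_stack()] with a `truth` attribute.
#' @export
synth_drop_image <- function(gamma, delta_rho, R0, pixel_scale,
                             blur_sd = 2, noise_sd = 0, seed = NULL,
                             g = 9.80665, theta_max = 2.6, margin = 0.2,
                             width = NULL, height = NULL) {
  if (!is.numeric(pixel_scale) || pixel_scale <= 0)
    stop_validation("'pixel_scale' must be > 0")
  if (!is.numeric(R0) || R0 <= 0)
    stop_validation("cannot render a blank frame: 'R0' must be > 0")
  out <- drop_outline(gamma, delta_rho, R0, g, n_points = 801, theta_max = theta_max)
  xpx <- out$x / pixel_scale
  zpx <- out$z / pixel_scale
  wd <- diff(range(xpx)); ht <- diff(range(zpx))
  nx <- width %||% ceiling(wd * (1 + 2 * margin))
  nz <- height %||% ceiling(ht * (1 + 2 * margin))
  if (wd > nx || ht > nz)
    stop_validation("drop (%.0f x %.0f px) does not fit in the %d x %d frame",
                    wd, ht, nx, nz)
  cx <- nx / 2
  cz <- (nz - ht) / 2
  poly <- cbind(xpx + cx, zpx + cz)
  poly <- rbind(poly, poly[1, ])          # close across the substrate chord
  gx <- rep(seq_len(nx) - 0.5, times = nz)
  gz <- rep(seq_len(nz) - 0.5, each = nx)
  inside <- mgcv::in.out(poly, cbind(gx, gz))
  m <- matrix(as.numeric(inside), nrow = nx, ncol = nz)
  if (blur_sd > 0) m <- EBImage::gblur(m, sigma = blur_sd)
  if (noise_sd > 0) m <- m + with_seed(seed, stats::rnorm(length(m), 0, noise_sd))
  m <- pmin(pmax(m, 0), 1)
  img <- image_stack(m, pixel_scale, channel = "synthetic")
  attr(img, "truth") <- list(gamma = gamma, delta_rho = delta_rho, R0 = R0,
                             g = g, bond = delta_rho * g * R0^2 / gamma,
                             apex_px = c(cx, cz), contour_px = poly,
                             blur_sd = blur_sd, noise_sd = noise_sd, seed = seed)
  img
}

#' Force trace container
#'
#' A force-versus-time record from a parallel-plate push-back test.
#'
#' @param t times (s), strictly increasing.
#' @param force forces (N), same length as `t`.
#' @param preload applied contact preload (N); the protocol targets
#'   0.2-0.3 uN.
#' @param source metadata list (tissue, stage time relative to gastrulation
#'   onset).
#' @param truth ground-truth list attached by the generator.
#' @return Object of class `force_trace`.
#' @export
force_trace <- function(t, force, preload = NA_real_, source = list(),
                        truth = NULL) {
  if (length(t) != length(force))
    stop_validation("'t' and 'force' must have equal length")
  if (any(diff(t) <= 0)) stop_validation("'t' must be strictly increasing")
  structure(data.frame(t = t, force = force),
            preload = preload, source = source, truth = truth,
            class = c("force_trace", "data.frame"))
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("Force trace: %d samples over %.0f s, force %.3g to %.3g uN\n",
              nrow(x), diff(range(x$t)), 1e6 * min(x$force), 1e6 * max(x$force)))
  invisible(x)
}

#' Generate a synthetic push-back force trace
#'
#' Emulates the structure of thickening-force tests: initial stress
#' relaxation of a viscoelastic explant after preload, a plateau, and then a
#' push-back ramp from a known onset time. The deterministic trace is
#' \deqn{F(t) = \mathrm{preload} + a e^{-t/\tau} - a + \mathrm{plateau} +
#'       r \max(0, t - t_{on})}
#' plus i.i.d. Gaussian noise.
#'
#' @param duration trace length (s).
#' @param dt sampling interval (s), > 0.
#' @param preload applied contact force (N); default 0.25 uN, the middle of
#'   the 0.2-0.3 uN protocol band.
#' @param relax_amplitude amplitude `a` of the stress-relaxation decay (N).
#' @param relax_tau relaxation time constant (s).
#' @param plateau_level constant offset added to the post-relaxation plateau
#'   (N).
#' @param onset_time push-back onset (s); `NA` or `Inf` (or `ramp_rate = 0`)
#'   gives a trace with no onset, which is a valid null case.
#' @param ramp_rate push-back ramp slope (N/s); default 1.7e-10 N/s, i.e.
#'   about 0.3 uN gained over 30 min, the scale of measured thickening
#'   forces.
#' @param noise_sd force noise SD (N); default 1e-8 N (0.01 uN,
#'   instrument-scale).
#' @param seed integer seed.
#' @return A [force_trace()] with truth in metadata.
#' @export
synth_pushback_trace <- function(duration = 7200, dt = 1,
                                 preload = 2.5e-7, relax_amplitude = 1e-7,
                                 relax_tau = 60, plateau_level = 0,
                                 onset_time = 3600, ramp_rate = 1.7e-10,
                                 noise_sd = 1e-8, seed = NULL) {
  if (dt <= 0) stop_validation("'dt' must be > 0")
  if (noise_sd < 0) stop_validation("'noise_sd' must be >= 0")
  if (relax_tau <= 0) stop_validation("'relax_tau' must be > 0")
  t <- seq(0, duration, by = dt)
  onset <- if (is.na(onset_time)) Inf else onset_time
  f <- preload + relax_amplitude * exp(-t / relax_tau) - relax_amplitude +
    plateau_level + ramp_rate * pmax(0, t - onset)
  f <- f + with_seed(seed, stats::rnorm(length(t), 0, noise_sd))
  has_onset <- is.finite(onset) && ramp_rate != 0 && onset < duration
  force_trace(t, f, preload = preload,
              source = list(kind = "synthetic_pushback"),
              truth = list(preload = preload, relax_amplitude = relax_amplitude,
                           relax_tau = relax_tau, plateau_level = plateau_level,
                           onset_time = if (has_onset) onset else NA_real_,
                           ramp_rate = ramp_rate, noise_sd = noise_sd,
                           seed = seed))
}

#' Track table container
#'
#' Fiduciary-point tracks from time-lapse sequences: one row per point per
#' time, with times in hours relative to gastrulation onset (G).
#'
#' @param df data frame with columns `point_id`, `region`, `t`, `x`, `y`.
#' @param pairs named list mapping each region to the two `point_id`s whose
#'   separation defines the regional width.
#' @param truth optional generator ground truth.
#' @return Object of class `track_table`.
#' @export
track_table <- function(df, pairs = NULL, truth = NULL) {
  need <- c("point_id", "region", "t", "x", "y")
  if (!all(need %in% names(df)))
    stop_validation("track table needs columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(df[, c("point_id", "t")]))
    stop_validation("(point_id, t) pairs must be unique")
  structure(as.data.frame(df)[, need],
            pairs = pairs, truth = truth,
            class = c("track_table", "data.frame"))
}

#' Generate synthetic fiduciary-point tracks with known convergence regimes
#'
#' For each region, places a pair of boundary points whose separation follows
#' \eqn{W(t)/W_i = 1 - r(t) (t - t_0)} piecewise-linearly (continuous) around
#' an optional changepoint, with rates in percent of initial width per hour,
#' plus isotropic positional noise. The default regimes are the study
#' conditions for marginal-zone convergence: IMZ at a constant 10 %/hr and
#' NIMZ at 7 %/hr slowing to 0 %/hr at a changepoint of -0.7 h (i.e. about
#' 40 min before gastrulation onset).
#'
#' @param regions data frame with columns `label`, `rate_before`,
#'   `rate_after` (percent/hr) and `changepoint` (hr; `NA` for a single
#'   regime).
#' @param t_start,t_end time span (hr relative to G).
#' @param dt sampling interval (hr); default 0.05 h = 3 min, the typical
#'   time-lapse frame interval.
#' @param initial_width initial pair separation (m); default 1 mm.
#' @param positional_noise_sd per-coordinate noise SD (m); default 3 um,
#'   about one pixel of manual tracking error.
#' @param seed integer seed.
#' @return A [track_table()]; truth metadata records the regime parameters.
#' @export
synth_track_table <- function(regions = data.frame(
                                label = c("IMZ", "NIMZ"),
                                rate_before = c(10, 7),
                                rate_after = c(10, 0),
                                changepoint = c(NA, -0.7)),
                              t_start = -2, t_end = 2, dt = 0.05,
                              initial_width = 1e-3,
                              positional_noise_sd = 3e-6, seed = NULL) {
  if (dt <= 0) stop_validation("'dt' must be > 0")
  if (t_end <= t_start) stop_validation("'t_end' must exceed 't_start'")
  if (anyDuplicated(regions$label)) stop_validation("region labels must be unique")
  if (!all(is.finite(regions$rate_before)) || !all(is.finite(regions$rate_after)))
    stop_validation("rates must be finite")
  t <- seq(t_start, t_end, by = dt)
  ratio_fun <- function(rb, ra, cp) {
    if (is.na(cp)) cp <- Inf
    1 - (rb / 100) * (pmin(t, cp) - t_start) - (ra / 100) * pmax(0, t - cp)
  }
  rows <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    lab <- as.character(regions$label[i])
    ratio <- ratio_fun(regions$rate_before[i], regions$rate_after[i],
                       regions$changepoint[i])
    if (any(ratio <= 0))
      stop_validation(
        "over-convergence: region '%s' width driven to <= 0 within the time span", lab)
    w <- initial_width * ratio
    y0 <- (i - 1) * 2 * initial_width
    noise <- with_seed(
      if (is.null(seed)) NULL else seed + i,
      matrix(stats::rnorm(4 * length(t), 0, positional_noise_sd), ncol = 4))
    rows[[i]] <- data.frame(
      point_id = rep(paste0(lab, c("_L", "_R")), each = length(t)),
      region = lab,
      t = rep(t, 2),
      x = c(-w / 2 + noise[, 1], w / 2 + noise[, 2]),
      y = c(y0 + noise[, 3], y0 + noise[, 4]))
  }
  df <- do.call(rbind, rows)
  pairs <- stats::setNames(
    lapply(as.character(regions$label), function(l) paste0(l, c("_L", "_R"))),
    as.character(regions$label))
  track_table(df, pairs = pairs,
              truth = list(regions = regions, t_start = t_start, t_end = t_end,
                           dt = dt, initial_width = initial_width,
                           positional_noise_sd = positional_noise_sd,
                           seed = seed))
}

# --- plain-text serialization -------------------------------------------------

write_truth_sidecar <- function(obj, file) {
  tr <- attr(obj, "truth")
  if (!is.null(tr)) {
    tr <- lapply(tr, function(v) if (is.data.frame(v)) as.list(v) else v)
    yaml::write_yaml(tr, paste0(file, ".yaml"))
  }
  invisible(file)
}

#' Write / read a contour as CSV (columns x, z in meters)
#'
#' Ground truth, when present, goes to a YAML sidecar `<file>.yaml`.
#' @param contour an [observed_contour()].
#' @param file path.
#' @param sidecar also write the truth sidecar?
#' @export
write_contour_csv <- function(contour, file, sidecar = TRUE) {
  stopifnot(inherits(contour, "observed_contour"))
  utils::write.csv(as.data.frame(contour), file, row.names = FALSE)
  if (sidecar) write_truth_sidecar(contour, file)
  invisible(file)
}

#' @rdname write_contour_csv
#' @param pixel_scale m/pixel recorded on the read contour.
#' @export
read_contour_csv <- function(file, pixel_scale = NA_real_) {
  observed_contour(utils::read.csv(file), pixel_scale = pixel_scale,
                   source = list(file = file))
}

#' Write / read a force trace as CSV (columns t, force; s and N)
#' @param trace a [force_trace()].
#' @param file path.
#' @param sidecar also write the truth sidecar?
#' @export
write_trace_csv <- function(trace, file, sidecar = TRUE) {
  stopifnot(inherits(trace, "force_trace"))
  utils::write.csv(as.data.frame(trace), file, row.names = FALSE)
  if (sidecar) write_truth_sidecar(trace, file)
  invisible(file)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(file) {
  df <- utils::read.csv(file)
  force_trace(df$t, df$force, source = list(file = file))
}

#' Write / read a track table as CSV (point_id, region, t, x, y)
#' @param tracks a [track_table()].
#' @param file path.
#' @param sidecar also write the truth sidecar?
#' @export
write_tracks_csv <- function(tracks, file, sidecar = TRUE) {
  stopifnot(inherits(tracks, "track_table"))
  utils::write.csv(as.data.frame(tracks), file, row.names = FALSE)
  if (sidecar) write_truth_sidecar(tracks, file)
  invisible(file)
}

#' @rdname write_tracks_csv
#' @param pairs region-to-point-pair mapping for the read table.
#' @export
read_tracks_csv <- function(file, pairs = NULL) {
  track_table(utils::read.csv(file), pairs = pairs)
}

#' Write an image stack as TIFF
#'
#' Single- or multi-page grayscale TIFF via the \pkg{tiff} writer in
#' \pkg{EBImage}.
#' @param img an [image_stack()].
#' @param file path.
#' @export
write_image_tiff <- function(img, file) {
  stopifnot(inherits(img, "image_stack"))
  EBImage::writeImage(EBImage::Image(img$data), file, type = "tiff")
  invisible(file)
}
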