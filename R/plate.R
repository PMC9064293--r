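# Parallel-plate compression tensiometry and push-back (thickening-force)
# trace analysis.

#' Surface tension from parallel-plate compression geometry
#'
#' Evaluates the compression-tensiometry relation
#' \deqn{\sigma = \frac{F}{\pi R_3^2 (1/R_1 + 1/R_2) - 2\pi R_3 \sin A}}
#' where `F` is the applied force read after stress relaxation (3 minutes in
#' the standard protocol), `R1` and `R2` are the principal radii of the
#' ellipsoidal aggregate profile (the formula is symmetric in them), `R3` is
#' the radius of the plate contact area, and `A` is the contact angle with
#' the plate. With all lengths in meters and `F` in newtons, `sigma` is in
#' N/m.
#'
#' @param force applied force at the relaxation reading (N).
#' @param R1,R2 principal profile radii (m), > 0. Identified here as the
#'   equatorial (azimuthal) and meridional radii; a swap changes nothing.
#' @param R3 contact-area radius (m), > 0.
#' @param A contact angle with the plate (rad), in (0, pi).
#' @return Surface tension (N/m).
#' @examples
#' plate_sigma(0.5e-6, 250e-6, 80e-6, 150e-6, 60 * pi / 180)  # ~1.43e-3 N/m
#' @export
plate_sigma <- function(force, R1, R2, R3, A) {
  if (any(!is.finite(c(force, R1, R2, R3, A))))
    stop_validation("all plate-geometry inputs must be finite")
  if (any(c(R1, R2, R3) <= 0)) stop_validation("all radii must be > 0")
  if (A <= 0 || A >= pi) stop_validation("contact angle 'A' must be in (0, pi)")
  denom <- pi * R3^2 * (1 / R1 + 1 / R2) - 2 * pi * R3 * sin(A)
  if (denom <= 0)
    stop("plate geometry error: contact term dominates (denominator <= 0); ",
         "shape inconsistent with a compressed drop", call. = FALSE)
  force / denom
}

#' Compression strain with protocol regime flag
#'
#' Engineering strain \eqn{\epsilon = (h_0 - h)/h_0} of a compressed
#' aggregate, flagged against the working band of 18-22 % strain: above 22 %
#' aggregates respond solid-like (interfacial tension readings rise
#' suddenly), below 18 % the reading is under-compressed relative to
#' protocol.
#'
#' @param h0 pre-compression height (m), > 0.
#' @param h compressed height (m), 0 < h <= h0.
#' @return List with `strain` and `regime` (one of `"in_protocol"`,
#'   `"solid_like_regime"`, `"below_protocol"`).
#' @export
compute_strain <- function(h0, h) {
  if (h0 <= 0 || h <= 0) stop_validation("heights must be > 0")
  if (h > h0) stop_validation("compressed height exceeds initial height (h > h0)")
  eps <- (h0 - h) / h0
  regime <- if (eps > 0.22) "solid_like_regime"
            else if (eps < 0.18) "below_protocol"
            else "in_protocol"
  list(strain = eps, regime = regime)
}

#' Decompose a push-back force trace
#'
#' Analyzes a thickening-force record from a held-platen test: the explant
#' first stress-relaxes (viscoelastic decay), plateaus, then pushes back
#' with rising force as it rounds and thickens. The trace is median-smoothed,
#' the relaxation segment is fit with a single exponential
#' `F = a + b exp(-t/tau)`, the plateau force and the noise SD are estimated
#' after relaxation, and the onset is the first time the smoothed force
#' exceeds `plateau + k * noise_sd` and stays above for a sustained window.
#' The detected crossing is refined by intersecting a line fit to the early
#' ramp with the plateau level, which removes the threshold-crossing lag.
#'
#' The force gain over 30 minutes is reported both from the detected onset
#' (`delta_F_30min`) and from the start of the test
#' (`delta_F_30min_from_start`), since protocols differ on the reference
#' point.
#'
#' @param trace a [force_trace()].
#' @param k onset threshold in noise SDs above the plateau (default 3).
#' @param sustain sustained-excursion window (s, default 600 = 10 min);
#'   at least `sustain_frac` of the smoothed samples in the window must
#'   exceed the threshold.
#' @param sustain_frac fraction of window samples required above threshold.
#' @param smooth_window moving-median window (samples, odd; default 5).
#' @param relax_read_time the protocol's post-relaxation reading time (s,
#'   default 180).
#' @param plateau_window window after relaxation used to estimate the
#'   plateau force (s).
#' @return Object of class `pushback_fit`: `relaxation` (a, b, tau,
#'   converged), `relaxation_end` (s), `plateau_force` (N), `noise_sd` (N),
#'   `onset_time` (s or NA), `delta_F_30min`, `delta_F_30min_from_start`
#'   (N), and flags.
#' @export
analyze_pushback <- function(trace, k = 3, sustain = 600, sustain_frac = 0.9,
                             smooth_window = 5, relax_read_time = 180,
                             plateau_window = 600) {
  stopifnot(inherits(trace, "force_trace"))
  t <- trace$t; f <- trace$force
  if (diff(range(t)) < relax_read_time + plateau_window)
    stop("trace too short for push-back analysis (needs at least the ",
         "relaxation and plateau windows)", call. = FALSE)
  if (smooth_window %% 2 == 0) smooth_window <- smooth_window + 1
  fs <- stats::runmed(f, smooth_window)
  # -- relaxation segment fit on the early trace
  i_rel <- t <= max(relax_read_time * 3, min(t) + 0.25 * diff(range(t)))
  a0 <- stats::median(f[t > relax_read_time & t <= relax_read_time + plateau_window])
  b0 <- f[1] - a0
  relax <- tryCatch({
    ft <- minpack.lm::nlsLM(ff ~ a + b * exp(-tt / tau),
                            data = data.frame(tt = t[i_rel], ff = f[i_rel]),
                            start = list(a = a0, b = b0, tau = relax_read_time / 3),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(ft)
    list(a = unname(cf["a"]), b = unname(cf["b"]), tau = unname(cf["tau"]),
         converged = TRUE)
  }, error = function(e) list(a = a0, b = b0, tau = relax_read_time / 3,
                              converged = FALSE))
  relaxation_end <- min(max(t), max(relax_read_time, 5 * abs(relax$tau)))
  # -- plateau and noise
  i_pl <- t >= relaxation_end & t <= relaxation_end + plateau_window
  plateau <- stats::median(fs[i_pl])
  noise_sd <- stats::mad(f - fs)
  thr <- plateau + k * noise_sd
  # -- sustained excursion above threshold
  cand <- which(t >= relaxation_end & fs > thr)
  onset <- NA_real_
  dt_med <- stats::median(diff(t))
  for (i in cand) {
    win <- which(t >= t[i] & t <= t[i] + sustain)
    if (length(win) < max(3, 0.5 * sustain / dt_med)) break  # window exceeds trace
    if (mean(fs[win] > thr) >= sustain_frac) { onset <- t[i]; break }
  }
  flags <- character(0)
  if (!is.na(onset)) {
    # refine: intersect the early-ramp line with the plateau level
    win <- which(t >= onset & t <= onset + sustain)
    if (length(win) >= 3) {
      lf <- stats::lm.fit(cbind(1, t[win]), fs[win])
      sl <- lf$coefficients[2]
      if (is.finite(sl) && sl > 0) {
        onset_ref <- (plateau - lf$coefficients[1]) / sl
        onset <- min(max(onset_ref, relaxation_end), onset)
      }
    }
  } else {
    flags <- c(flags, "no_onset")
  }
  d30 <- NA_real_; d30s <- NA_real_
  fs_at <- stats::approxfun(t, fs, rule = 2)
  if (!is.na(onset)) {
    if (onset + 1800 <= max(t)) d30 <- fs_at(onset + 1800) - fs_at(onset)
    else flags <- c(flags, "trace_shorter_than_30min_after_onset")
  }
  if (min(t) + 1800 <= max(t)) d30s <- fs_at(min(t) + 1800) - fs_at(min(t))
  structure(list(relaxation = relax, relaxation_end = relaxation_end,
                 plateau_force = plateau, noise_sd = noise_sd,
                 onset_time = onset, delta_F_30min = d30,
                 delta_F_30min_from_start = d30s,
                 k = k, sustain = sustain, smooth_window = smooth_window,
                 flags = flags, trace = trace),
            class = "pushback_fit")
}

#' @export
print.pushback_fit <- function(x, ...) {
  cat("Push-back trace analysis\n")
  cat(sprintf("  relaxation: tau = %.3g s (%s), end at %.0f s\n",
              x$relaxation$tau,
              if (x$relaxation$converged) "exp fit" else "fallback",
              x$relaxation_end))
  cat(sprintf("  plateau force = %.4g uN, noise SD = %.3g uN\n",
              1e6 * x$plateau_force, 1e6 * x$noise_sd))
  if (is.na(x$onset_time)) {
    cat("  onset: none detected\n")
  } else {
    cat(sprintf("  onset at %.0f s; dF(30 min from onset) = %.4g uN\n",
                x$onset_time, 1e6 * x$delta_F_30min))
  }
  if (!is.na(x$delta_F_30min_from_start))
    cat(sprintf("  dF(30 min from start) = %.4g uN\n",
                1e6 * x$delta_F_30min_from_start))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.pushback_fit <- function(object, ...) object

#' @export
plot.pushback_fit <- function(x, ...) {
  tr <- x$trace
  plot(tr$t, 1e6 * tr$force, type = "l", col = "gray",
       xlab = "t (s)", ylab = "force (uN)", main = "Push-back trace", ...)
  graphics::lines(tr$t, 1e6 * stats::runmed(tr$force, x$smooth_window), col = "black")
  graphics::abline(h = 1e6 * x$plateau_force, col = "blue", lty = 2)
  graphics::abline(h = 1e6 * (x$plateau_force + x$k * x$noise_sd), col = "blue", lty = 3)
  if (!is.na(x$onset_time)) graphics::abline(v = x$onset_time, col = "red")
  invisible(x)
}
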