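# Axisymmetric drop shape analysis: estimate tension by optimally fitting
# integrated Young-Laplace profiles to an observed aggregate outline.

# Canonical model outline for (R0, Bo): both halves of the profile, apex at
# the origin. The capillary constant is c = Bo / R0^2, so the shape depends
# on (R0, Bo) only; gamma enters afterwards through gamma = drho * g * R0^2 / Bo.
model_outline <- function(R0, Bo, theta_stop = pi, n_out = 250, rel_tol = 1e-7) {
  ctx <- structure(list(gamma = 1, delta_rho = Bo / (R0^2 * 9.80665),
                        g = 9.80665, capillary_constant = Bo / R0^2),
                   class = "fluid_context")
  p <- integrate_profile(ctx, R0, theta_stop = theta_stop,
                         rel_tol = rel_tol, n_out = n_out)
  nx <- c(-rev(p$x), p$x[-1])
  nz <- c(rev(p$z), p$z[-1])
  list(x = nx, z = nz)
}

# Fast unit-R0 outline by fixed-step RK4, for the simplex search stages (the
# shape is exactly scale-equivariant, so only Bo matters here; the polish
# stage re-evaluates through the adaptive integrator). Step truncation at
# n_steps = 400 over s in [0, 2*theta_stop] is ~(h)^4 ~ 1e-8 relative.
outline_rk4_unit <- function(Bo, theta_stop = pi, n_steps = 400) {
  s0 <- 1e-4
  h <- (2 * theta_stop - s0) / n_steps
  x <- s0 - s0^3 / 6; z <- s0^2 / 2; th <- s0
  xs <- numeric(n_steps + 1); zs <- numeric(n_steps + 1)
  xs[1] <- x; zs[1] <- z
  kfin <- n_steps + 1L
  for (i in seq_len(n_steps)) {
    k1x <- cos(th); k1z <- sin(th); k1t <- 2 + Bo * z - k1z / x
    x2 <- x + h / 2 * k1x; z2 <- z + h / 2 * k1z; t2 <- th + h / 2 * k1t
    k2x <- cos(t2); k2z <- sin(t2); k2t <- 2 + Bo * z2 - k2z / x2
    x3 <- x + h / 2 * k2x; z3 <- z + h / 2 * k2z; t3 <- th + h / 2 * k2t
    k3x <- cos(t3); k3z <- sin(t3); k3t <- 2 + Bo * z3 - k3z / x3
    x4 <- x + h * k3x; z4 <- z + h * k3z; t4 <- th + h * k3t
    k4x <- cos(t4); k4z <- sin(t4); k4t <- 2 + Bo * z4 - k4z / x4
    x <- x + h / 6 * (k1x + 2 * k2x + 2 * k3x + k4x)
    z <- z + h / 6 * (k1z + 2 * k2z + 2 * k3z + k4z)
    th <- th + h / 6 * (k1t + 2 * k2t + 2 * k3t + k4t)
    xs[i + 1L] <- x; zs[i + 1L] <- z
    if (th >= theta_stop || x < 0) { kfin <- i + 1L; break }
  }
  xs <- xs[seq_len(kfin)]; zs <- zs[seq_len(kfin)]
  list(x = c(-rev(xs), 0, xs), z = c(rev(zs), 0, zs))
}

adsa_params_unpack <- function(p, scale, fit_tilt) {
  list(R0 = exp(p[1]), Bo = exp(p[2]),
       x0 = p[3] * scale, z0 = p[4] * scale,
       tilt = if (fit_tilt) p[5] else 0)
}

adsa_objective <- function(p, contour, scale, fit_tilt,
                           n_out = 250, rel_tol = 1e-7, fast = FALSE) {
  q <- adsa_params_unpack(p, scale, fit_tilt)
  if (!is.finite(q$R0) || !is.finite(q$Bo) || q$Bo > 50 || q$Bo < 1e-8 ||
      q$R0 > 1e3 * scale || q$R0 < 1e-3 * scale)
    return(1e6)
  mo <- tryCatch(
    if (fast) {
      u <- outline_rk4_unit(q$Bo)
      list(x = q$R0 * u$x, z = q$R0 * u$z)
    } else model_outline(q$R0, q$Bo, n_out = n_out, rel_tol = rel_tol),
    error = function(e) NULL)
  if (is.null(mo)) return(1e6)
  vx <- mo$x; vz <- mo$z
  if (q$tilt != 0) {
    rx <- vx * cos(q$tilt) - vz * sin(q$tilt)
    rz <- vx * sin(q$tilt) + vz * cos(q$tilt)
    vx <- rx; vz <- rz
  }
  d <- polyline_min_dist(contour$x, contour$z, vx + q$x0, vz + q$z0)
  mean(d^2) / scale^2
}

#' Fit tissue tension by axisymmetric drop shape analysis
#'
#' Minimizes the sum of squared nearest-point distances between an observed
#' aggregate outline and integrated Young-Laplace profiles, over apex radius,
#' Bond number, apex position, and optionally tilt. Fitting in
#' \eqn{(Bo, R_0)} rather than \eqn{(\gamma, R_0)} improves conditioning
#' (tension and apex radius are strongly correlated in raw form); the tension
#' is recovered afterwards as \eqn{\gamma = \Delta\rho\, g\, R_0^2 / Bo}.
#' A derivative-free simplex search is run from three starts bracketing the
#' contour's apex-curvature estimate, followed by a polish at fine
#' integration tolerance.
#'
#' Near-spherical shapes carry no tension information under gravity
#' flattening: when the fitted Bond number falls below `bo_min` the fit is
#' flagged unidentifiable (the shape is consistent with any sufficiently
#' large tension).
#'
#' @param contour an [observed_contour()].
#' @param delta_rho density difference tissue minus medium (kg/m^3), > 0;
#'   must be supplied (the tissue density is an input, not a default).
#' @param g gravitational acceleration (m/s^2).
#' @param fit_tilt also fit a rotation about the apex? Default `FALSE`.
#' @param bo_min identifiability threshold on the fitted Bond number;
#'   default 0.05 (below this, gravity deformation is under typical contour
#'   noise).
#' @param qc check contour QC first (computing it if absent) and refuse
#'   contours that fail? Default `TRUE`.
#' @param control list of optimizer/integrator settings: `maxit` (400),
#'   `n_starts` (3), `n_out` (250) and `rel_tol` (1e-7) during search,
#'   `n_out_final` (600) and `rel_tol_final` (1e-9) for the polish and
#'   reported residuals.
#' @return Object of class `adsa_fit` with components `gamma` (N/m), `R0`,
#'   `bond`, `apex` (x0, z0), `tilt`, `rms_residual` (m), `identifiable`,
#'   `converged`, `n_iter`, plus the contour and settings. Standard methods
#'   (`print`, `summary`, `coef`, `residuals`, `predict`, `plot`) apply.
#' @examples
#' \donttest{
#' cont <- synth_drop_contour(0.22e-3, 40, 7.5e-4, seed = 1)
#' fit <- fit_adsa(cont, delta_rho = 40)
#' coef(fit)["gamma"]
#' }
#' @export
fit_adsa <- function(contour, delta_rho, g = 9.80665, fit_tilt = FALSE,
                     bo_min = 0.05, qc = TRUE, control = list()) {
  stopifnot(inherits(contour, "observed_contour"))
  if (missing(delta_rho) || !is.numeric(delta_rho) || delta_rho <= 0)
    stop_validation("'delta_rho' must be supplied and > 0 for tension fitting")
  ctl <- utils::modifyList(list(maxit = 400, maxit_explore = 150, n_starts = 3,
                                n_out = 150, rel_tol = 1e-6, n_out_final = 500,
                                rel_tol_final = 1e-9), control)
  if (qc) {
    q <- attr(contour, "qc") %||% qc_contour(contour)
    if (!q$accepted)
      stop("contour rejected by QC (circularity ", signif(q$circularity, 3),
           ", convexity deficiency ", signif(q$convexity_deficiency, 3),
           "); too irregular for drop-shape analysis", call. = FALSE)
  }
  # initialize from a circle fit to the apex-most 30% of points
  zc <- contour$z
  near <- order(zc)[seq_len(max(10L, round(0.3 * nrow(contour))))]
  cf <- fit_circle(contour$x[near], contour$z[near])
  R0_init <- cf$r
  apex_init <- c(cf$cx, cf$cy - cf$r)
  scale <- R0_init
  starts <- lapply(c(0.7, 1, 1.4)[seq_len(ctl$n_starts)], function(f) {
    p <- c(log(R0_init * f), log(1), apex_init[1] / scale, apex_init[2] / scale)
    if (fit_tilt) p <- c(p, 0)
    p
  })
  # stage 1: cheap exploratory simplex from each start
  best <- NULL
  n_iter <- 0L
  for (p0 in starts) {
    opt <- stats::optim(p0, adsa_objective, contour = contour, scale = scale,
                        fit_tilt = fit_tilt, fast = TRUE,
                        method = "Nelder-Mead",
                        control = list(maxit = ctl$maxit_explore, reltol = 1e-7))
    n_iter <- n_iter + opt$counts[1]
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  # stage 2: refine the best start at search tolerance
  ref <- stats::optim(best$par, adsa_objective, contour = contour, scale = scale,
                      fit_tilt = fit_tilt, fast = TRUE,
                      method = "Nelder-Mead",
                      control = list(maxit = ctl$maxit, reltol = 1e-10))
  n_iter <- n_iter + ref$counts[1]
  # stage 3: polish at fine integration tolerance
  pol <- stats::optim(ref$par, adsa_objective, contour = contour, scale = scale,
                      fit_tilt = fit_tilt, n_out = ctl$n_out_final,
                      rel_tol = ctl$rel_tol_final,
                      method = "Nelder-Mead",
                      control = list(maxit = ctl$maxit, reltol = 1e-10))
  n_iter <- n_iter + pol$counts[1]
  q <- adsa_params_unpack(pol$par, scale, fit_tilt)
  gamma_hat <- delta_rho * g * q$R0^2 / q$Bo
  mse <- adsa_objective(pol$par, contour, scale, fit_tilt,
                        n_out = ctl$n_out_final, rel_tol = ctl$rel_tol_final)
  structure(list(gamma = gamma_hat, R0 = q$R0, bond = q$Bo,
                 apex = c(x0 = q$x0, z0 = q$z0), tilt = q$tilt,
                 rms_residual = sqrt(mse) * scale,
                 identifiable = q$Bo >= bo_min,
                 converged = pol$convergence == 0 && pol$value < 1e6,
                 n_iter = as.integer(n_iter),
                 delta_rho = delta_rho, g = g, bo_min = bo_min,
                 fit_tilt = fit_tilt, scale = scale, par = pol$par,
                 control = ctl, contour = contour),
            class = "adsa_fit")
}

#' @export
print.adsa_fit <- function(x, ...) {
  cat("Axisymmetric drop shape analysis fit\n")
  cat(sprintf("  gamma = %.4g mN/m   R0 = %.4g mm   Bo = %.4g\n",
              1e3 * x$gamma, 1e3 * x$R0, x$bond))
  cat(sprintf("  rms residual = %.3g m over %d points; %s, %s\n",
              x$rms_residual, nrow(x$contour),
              if (x$converged) "converged" else "NOT converged",
              if (x$identifiable) "identifiable"
              else "UNIDENTIFIABLE (shape near-spherical; tension not constrained)"))
  invisible(x)
}

#' @export
coef.adsa_fit <- function(object, ...) {
  c(gamma = object$gamma, R0 = object$R0, bond = object$bond,
    x0 = unname(object$apex[1]), z0 = unname(object$apex[2]),
    tilt = object$tilt)
}

#' @export
residuals.adsa_fit <- function(object, ...) {
  mo <- predict(object)
  d <- polyline_min_dist(object$contour$x, object$contour$z, mo$x, mo$z)
  inside <- mgcv::in.out(cbind(c(mo$x, mo$x[1]), c(mo$z, mo$z[1])),
                         cbind(object$contour$x, object$contour$z))
  ifelse(inside, -d, d)
}

#' @export
predict.adsa_fit <- function(object, n_out = 400, ...) {
  mo <- model_outline(object$R0, object$bond, n_out = n_out,
                      rel_tol = object$control$rel_tol_final)
  vx <- mo$x; vz <- mo$z
  if (object$tilt != 0) {
    rx <- vx * cos(object$tilt) - vz * sin(object$tilt)
    rz <- vx * sin(object$tilt) + vz * cos(object$tilt)
    vx <- rx; vz <- rz
  }
  data.frame(x = vx + object$apex[1], z = vz + object$apex[2])
}

#' @export
summary.adsa_fit <- function(object, ...) {
  r <- residuals(object)
  structure(list(fit = object,
                 resid_summary = summary(r),
                 qc = attr(object$contour, "qc")),
            class = "summary.adsa_fit")
}

#' @export
print.summary.adsa_fit <- function(x, ...) {
  print(x$fit)
  cat("Signed residuals (m; negative = inside fitted profile):\n")
  print(x$resid_summary)
  if (!is.null(x$qc)) print(x$qc)
  invisible(x)
}

#' @export
plot.adsa_fit <- function(x, ...) {
  p <- predict(x)
  plot(x$contour$x, -x$contour$z, asp = 1, pch = 16, cex = 0.5,
       xlab = "x (m)", ylab = "-z (m, apex up)",
       main = sprintf("ADSA fit: gamma = %.3g mN/m, Bo = %.3g",
                      1e3 * x$gamma, x$bond), ...)
  graphics::lines(p$x, -p$z, col = "red", lwd = 2)
  invisible(x)
}

#' Machine-readable fit report
#'
#' One summary row per fit, with parameters, diagnostics and flags; a batch
#' (list of fits) gives one row each. Unidentifiable fits carry an explicit
#' note that the shape is near-spherical and the tension unconstrained.
#'
#' @param fit an `adsa_fit` or a list of them.
#' @return A data frame.
#' @export
fit_report <- function(fit) {
  if (inherits(fit, "adsa_fit")) fit <- list(fit)
  do.call(rbind, lapply(fit, function(f) {
    data.frame(gamma_mN_per_m = 1e3 * f$gamma, R0_m = f$R0, bond = f$bond,
               x0_m = unname(f$apex[1]), z0_m = unname(f$apex[2]),
               tilt_rad = f$tilt, rms_residual_m = f$rms_residual,
               converged = f$converged, identifiable = f$identifiable,
               n_iter = f$n_iter,
               note = if (f$identifiable) ""
                      else "shape near-spherical; tension not constrained",
               stringsAsFactors = FALSE)
  }))
}
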