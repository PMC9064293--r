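#' Capillarity context for the Young-Laplace model
#'
#' Bundles the physical constants of the sessile-drop capillarity model: the
#' tissue surface (or interfacial) tension \eqn{\gamma}, the density
#' difference \eqn{\Delta\rho} between aggregate and immersion medium, and
#' gravitational acceleration \eqn{g}. The derived capillary constant
#' \eqn{c = \Delta\rho g / \gamma} (1/m^2) controls how strongly gravity
#' flattens the equilibrium shape; the equilibrium condition is
#' \deqn{\Delta P + \Delta\rho g z = \gamma (1/R_1 + 1/R_2)}
#' with \eqn{z} the depth below the aggregate apex.
#'
#' @param gamma surface or interfacial tension (N/m), > 0.
#' @param delta_rho density difference tissue minus medium (kg/m^3), >= 0.
#'   There is no default: the tissue density must be supplied from
#'   configuration or measurement.
#' @param g gravitational acceleration (m/s^2). Default 9.80665.
#' @return An object of class `fluid_context`.
#' @examples
#' ctx <- fluid_context(gamma = 0.22e-3, delta_rho = 40)
#' ctx$capillary_constant
#' @export
fluid_context <- function(gamma, delta_rho, g = 9.80665) {
  if (!is.numeric(gamma) || length(gamma) != 1 || !is.finite(gamma) || gamma <= 0)
    stop_validation("'gamma' must be a single positive finite number (N/m)")
  if (!is.numeric(delta_rho) || length(delta_rho) != 1 || !is.finite(delta_rho) || delta_rho < 0)
    stop_validation("'delta_rho' must be a single finite number >= 0 (kg/m^3)")
  if (!is.numeric(g) || length(g) != 1 || !is.finite(g) || g <= 0)
    stop_validation("'g' must be a single positive finite number (m/s^2)")
  structure(list(gamma = gamma, delta_rho = delta_rho, g = g,
                 capillary_constant = delta_rho * g / gamma),
            class = "fluid_context")
}

#' @export
print.fluid_context <- function(x, ...) {
  cat("Fluid context (Young-Laplace capillarity)\n")
  cat(sprintf("  gamma     : %.4g mN/m\n", 1e3 * x$gamma))
  cat(sprintf("  delta_rho : %.4g kg/m^3\n", x$delta_rho))
  cat(sprintf("  g         : %.5f m/s^2\n", x$g))
  cat(sprintf("  capillary constant c = %.6g 1/m^2\n", x$capillary_constant))
  invisible(x)
}

# Apex series start for the arc-length system: avoids the sin(theta)/x
# singularity at s = 0 using the second-order expansion
#   x ~ s - s^3/(6 R0^2),  z ~ s^2/(2 R0),  theta ~ s/R0.
apex_series_state <- function(R0, s0) {
  c(x = s0 - s0^3 / (6 * R0^2), z = s0^2 / (2 * R0), theta = s0 / R0)
}

laplace_rhs_factory <- function(R0, cc) {
  function(s, y, parms) {
    k1 <- 2 / R0 + cc * y[2] - sin(y[3]) / y[1]
    list(c(cos(y[3]), sin(y[3]), k1))
  }
}

#' Integrate an axisymmetric Young-Laplace drop profile
#'
#' Forward model for ADSA: integrates the Bashforth-Adams arc-length system
#' \deqn{dx/ds = \cos\theta,\quad dz/ds = \sin\theta,\quad
#'       d\theta/ds = 2/R_0 + c\,z - \sin\theta/x}
#' from apex conditions \eqn{(x, z, \theta)(0) = (0, 0, 0)} (with the apex
#' limit \eqn{\sin\theta/x \to 1/R_0}), producing the theoretical sessile
#' drop shape for a hypothetical tension. `z` increases from the apex toward
#' the supporting substrate; a positive density difference (tissue denser
#' than medium) flattens the shape. Integration stops at arc length `s_max`
#' or when the tangent angle reaches `theta_stop`, whichever comes first.
#'
#' The apex singularity is handled by a series expansion for
#' \eqn{s < 10^{-4} R_0}, after which an adaptive integrator
#' ([deSolve::lsodar]) with relative tolerance `rel_tol` takes over.
#'
#' @param ctx a [fluid_context()].
#' @param R0 apex radius of curvature (m), > 0.
#' @param s_max maximum arc length (m); default `2 * theta_stop * R0`, ample
#'   for gravity-flattened shapes (flattening shortens the arc to a given
#'   tangent angle).
#' @param theta_stop tangent angle (rad) at which to stop; default `pi`.
#' @param rel_tol relative tolerance of the adaptive integrator.
#' @param n_out number of requested output samples along arc length.
#' @return Object of class `laplace_profile`: a data frame with columns
#'   `s, x, z, theta, R1, R2` (an apex row `s = 0` with `R1 = R2 = R0` is
#'   included) and attributes `R0`, `gamma`, `delta_rho`, `g`,
#'   `capillary_constant`, `bond` (the Bond number
#'   \eqn{Bo = \Delta\rho g R_0^2/\gamma}) and `apex_pressure`
#'   (\eqn{\Delta P_0 = 2\gamma/R_0}).
#' @seealso [profile_curvatures()], [laplace_residual()],
#'   [integrate_profile_fixed()]
#' @examples
#' ctx <- fluid_context(gamma = 0.22e-3, delta_rho = 40)
#' p <- integrate_profile(ctx, R0 = 7.5e-4)
#' attr(p, "bond")
#' @export
integrate_profile <- function(ctx, R0, s_max = NULL, theta_stop = pi,
                              rel_tol = 1e-9, n_out = 400) {
  stopifnot(inherits(ctx, "fluid_context"))
  if (!is.numeric(R0) || length(R0) != 1 || !is.finite(R0) || R0 <= 0)
    stop_validation("'R0' must be a single positive finite length (m)")
  if (is.null(s_max)) s_max <- 2 * theta_stop * R0
  if (s_max <= 0) stop_validation("'s_max' must be > 0")
  cc <- ctx$capillary_constant
  s0 <- 1e-4 * R0
  y0 <- apex_series_state(R0, s0)
  times <- seq(s0, s_max, length.out = n_out)
  root <- function(s, y, parms) c(y[3] - theta_stop, y[1])
  sol <- deSolve::lsodar(y0, times, laplace_rhs_factory(R0, cc), parms = NULL,
                         rtol = rel_tol, atol = rel_tol * R0 * 1e-3,
                         rootfunc = root)
  if (attr(sol, "istate")[1] < 0)
    stop("Young-Laplace integration failed (istate = ",
         attr(sol, "istate")[1], ") at R0 = ", signif(R0, 4),
         ", c = ", signif(cc, 4), call. = FALSE)
  sol <- as.data.frame(sol)
  names(sol) <- c("s", "x", "z", "theta")
  if (any(sol$x < 0))
    stop("Young-Laplace integration reached a non-physical state (x < 0)",
         call. = FALSE)
  # drop rows at the closure pole (x -> 0 as theta -> pi for a full sphere),
  # where the axisymmetric parametrization is singular
  sol <- sol[sol$x > 0.5 * s0, , drop = FALSE]
  prof <- rbind(data.frame(s = 0, x = 0, z = 0, theta = 0), sol)
  prof <- structure(prof,
                    R0 = R0, gamma = ctx$gamma, delta_rho = ctx$delta_rho,
                    g = ctx$g, capillary_constant = cc,
                    bond = ctx$delta_rho * ctx$g * R0^2 / ctx$gamma,
                    apex_pressure = 2 * ctx$gamma / R0,
                    class = c("laplace_profile", "data.frame"))
  profile_curvatures(prof)
}

#' Fixed-step fourth-order reference integrator for drop profiles
#'
#' Integrates the same arc-length system as [integrate_profile()] with a
#' classical fixed-step fourth-order Runge-Kutta scheme. Serves as an
#' independent cross-check of the adaptive path: at fine steps the two must
#' agree to well below measurement precision.
#'
#' @inheritParams integrate_profile
#' @param n_steps number of RK4 steps across `[0, s_max]`.
#' @param keep approximate number of rows to retain in the output (the full
#'   step sequence is thinned for memory).
#' @return A `laplace_profile`, as for [integrate_profile()].
#' @export
integrate_profile_fixed <- function(ctx, R0, s_max = NULL, theta_stop = pi,
                                    n_steps = 1e5, keep = 2000) {
  stopifnot(inherits(ctx, "fluid_context"))
  if (!is.numeric(R0) || length(R0) != 1 || !is.finite(R0) || R0 <= 0)
    stop_validation("'R0' must be a single positive finite length (m)")
  if (is.null(s_max)) s_max <- 2 * theta_stop * R0
  cc <- ctx$capillary_constant
  s0 <- 1e-4 * R0
  y <- apex_series_state(R0, s0)
  h <- (s_max - s0) / n_steps
  thin <- max(1L, floor(n_steps / keep))
  n_keep <- floor(n_steps / thin) + 1L
  out <- matrix(NA_real_, n_keep + 1L, 4L)
  out[1L, ] <- c(s0, y)
  krow <- 1L
  x <- y[[1]]; z <- y[[2]]; th <- y[[3]]
  s <- s0
  two_over_R0 <- 2 / R0
  for (i in seq_len(n_steps)) {
    k1x <- cos(th);              k1z <- sin(th)
    k1t <- two_over_R0 + cc * z - k1z / x
    x2 <- x + h / 2 * k1x; z2 <- z + h / 2 * k1z; t2 <- th + h / 2 * k1t
    k2x <- cos(t2); k2z <- sin(t2); k2t <- two_over_R0 + cc * z2 - k2z / x2
    x3 <- x + h / 2 * k2x; z3 <- z + h / 2 * k2z; t3 <- th + h / 2 * k2t
    k3x <- cos(t3); k3z <- sin(t3); k3t <- two_over_R0 + cc * z3 - k3z / x3
    x4 <- x + h * k3x; z4 <- z + h * k3z; t4 <- th + h * k3t
    k4x <- cos(t4); k4z <- sin(t4); k4t <- two_over_R0 + cc * z4 - k4z / x4
    x <- x + h / 6 * (k1x + 2 * k2x + 2 * k3x + k4x)
    z <- z + h / 6 * (k1z + 2 * k2z + 2 * k3z + k4z)
    th <- th + h / 6 * (k1t + 2 * k2t + 2 * k3t + k4t)
    s <- s0 + i * h
    if (i %% thin == 0L) {
      krow <- krow + 1L
      out[krow, ] <- c(s, x, z, th)
    }
    if (th >= theta_stop) {
      krow <- krow + 1L
      out[krow, ] <- c(s, x, z, th)
      break
    }
    if (x < 0) stop("RK4 reference integration reached x < 0", call. = FALSE)
  }
  out <- out[seq_len(krow), , drop = FALSE]
  out <- out[out[, 2] > 0.5 * s0, , drop = FALSE]
  prof <- rbind(data.frame(s = 0, x = 0, z = 0, theta = 0),
                stats::setNames(as.data.frame(out), c("s", "x", "z", "theta")))
  prof <- structure(prof,
                    R0 = R0, gamma = ctx$gamma, delta_rho = ctx$delta_rho,
                    g = ctx$g, capillary_constant = cc,
                    bond = ctx$delta_rho * ctx$g * R0^2 / ctx$gamma,
                    apex_pressure = 2 * ctx$gamma / R0,
                    class = c("laplace_profile", "data.frame"))
  profile_curvatures(prof)
}

#' Populate principal radii of curvature along a profile
#'
#' Fills the meridional radius \eqn{R_1 = 1/(d\theta/ds)} (evaluated through
#' the governing equation) and the azimuthal radius \eqn{R_2 = x/\sin\theta}
#' at every arc-length sample. The apex is an umbilic point where both limits
#' equal the apex radius \eqn{R_0}; no division by \eqn{\sin\theta = 0} is
#' performed there.
#'
#' @param p a `laplace_profile`.
#' @return The profile with columns `R1` and `R2` populated.
#' @export
profile_curvatures <- function(p) {
  stopifnot(inherits(p, "laplace_profile"))
  R0 <- attr(p, "R0"); cc <- attr(p, "capillary_constant")
  k1 <- 2 / R0 + cc * p$z - ifelse(p$s > 0, sin(p$theta) / p$x, 1 / R0)
  p$R1 <- 1 / k1
  p$R2 <- ifelse(p$s > 0, p$x / sin(p$theta), R0)
  p
}

#' Pointwise Young-Laplace residual of an integrated profile
#'
#' Checks that the housed equilibrium equation holds along the profile:
#' \eqn{|\Delta P_0 + \Delta\rho g z - \gamma(\kappa_1 + \kappa_2)| / \Delta P_0}
#' where the meridional curvature \eqn{\kappa_1 = d\theta/ds} is recomputed
#' independently by spline differentiation of the sampled \eqn{\theta(s)}
#' (not through the governing equation, which would be circular) and
#' \eqn{\kappa_2 = \sin\theta/x}.
#'
#' @param p a `laplace_profile`.
#' @return Numeric vector of relative residuals (apex row excluded).
#' @export
laplace_residual <- function(p) {
  stopifnot(inherits(p, "laplace_profile"))
  i <- which(p$s > 0)
  # drop near-duplicate abscissae (the root-stopping sample can land on top
  # of a grid point, which would corrupt the spline derivative at the end)
  ds <- diff(p$s[i])
  keep <- c(TRUE, ds > 0.25 * stats::median(ds))
  i <- i[keep]
  th_fun <- stats::splinefun(p$s[i], p$theta[i], method = "fmm")
  k1 <- th_fun(p$s[i], deriv = 1)
  k2 <- sin(p$theta[i]) / p$x[i]
  dp0 <- attr(p, "apex_pressure")
  lhs <- dp0 + attr(p, "delta_rho") * attr(p, "g") * p$z[i]
  rhs <- attr(p, "gamma") * (k1 + k2)
  abs(lhs - rhs) / dp0
}

#' Equatorial radius of a drop profile
#'
#' The radial coordinate where the tangent angle crosses \eqn{\pi/2},
#' obtained by spline interpolation of \eqn{x(\theta)} near the crossing.
#' `NA` if the profile never reaches the equator.
#'
#' @param p a `laplace_profile`.
#' @return length (m), or `NA`.
#' @export
equatorial_radius <- function(p) {
  stopifnot(inherits(p, "laplace_profile"))
  if (max(p$theta) < pi / 2) return(NA_real_)
  i <- which(p$theta > 0.1 & p$theta < pi - 0.1)
  if (length(i) < 4) i <- which(p$s > 0)
  stats::spline(p$theta[i], p$x[i], xout = pi / 2, method = "natural")$y
}

#' @export
print.laplace_profile <- function(x, ...) {
  cat(sprintf(
    "Young-Laplace profile: R0 = %.4g m, Bo = %.4g, gamma = %.4g mN/m, %d samples, theta max = %.3f rad\n",
    attr(x, "R0"), attr(x, "bond"), 1e3 * attr(x, "gamma"), nrow(x), max(x$theta)))
  invisible(x)
}

#' Export a profile to CSV
#'
#' Writes columns `s, x, z, theta, R1, R2` (SI units) for plotting or for the
#' fitting module.
#' @param p a `laplace_profile`.
#' @param file path to write.
#' @export
write_profile_csv <- function(p, file) {
  stopifnot(inherits(p, "laplace_profile"))
  utils::write.csv(as.data.frame(p)[, c("s", "x", "z", "theta", "R1", "R2")],
                   file, row.names = FALSE)
  invisible(file)
}
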