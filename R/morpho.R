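# Time-lapse morphometrics: regional convergence and thickening ratios, rate
# and changepoint estimation, spherical-geometry-corrected areas, blastopore
# closure, cell-shape metrics, and the group summaries used for reporting.

#' Regional width series from fiduciary-point tracks
#'
#' For each region, the width `W_t` is the Euclidean separation of its
#' declared boundary-point pair at each shared time, and the convergence
#' ratio `W_t / W_i` is normalized to the first shared time (so the first
#' ratio is 1 by construction). Width is the straight-line point separation,
#' not arc length: the measurements are made on 2-D projections of
#' approximately flat explants. Times missing from either point of a pair
#' are omitted with a message.
#'
#' @param tracks a [track_table()].
#' @param pairs named list `region -> c(point_id_A, point_id_B)`; defaults
#'   to the mapping carried by the track table.
#' @return Object of class `region_series`: data frame with columns
#'   `region, t, width, ratio` and an attribute `initial_width` (named per
#'   region).
#' @export
region_widths <- function(tracks, pairs = attr(tracks, "pairs")) {
  stopifnot(inherits(tracks, "track_table"))
  if (is.null(pairs)) stop_validation("no region -> point-pair mapping supplied")
  out <- list(); wi <- numeric(0)
  for (reg in names(pairs)) {
    ids <- pairs[[reg]]
    a <- tracks[tracks$point_id == ids[1], ]
    b <- tracks[tracks$point_id == ids[2], ]
    tt <- intersect(a$t, b$t)
    n_drop <- length(union(a$t, b$t)) - length(tt)
    if (n_drop > 0)
      message(sprintf("region_widths: region '%s': %d unmatched timepoint(s) omitted",
                      reg, n_drop))
    if (length(tt) == 0) stop_validation("region '%s': no shared timepoints", reg)
    tt <- sort(tt)
    a <- a[match(tt, a$t), ]; b <- b[match(tt, b$t), ]
    w <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
    if (w[1] <= 0) stop_validation("region '%s': initial width must be > 0", reg)
    wi[reg] <- w[1]
    out[[reg]] <- data.frame(region = reg, t = tt, width = w, ratio = w / w[1])
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  structure(df, initial_width = wi,
            class = c("region_series", "data.frame"))
}

#' Build a region series from precomputed ratios
#'
#' For thickness (`T_t/T_i`) or area (`A_t/A_i`) series measured directly,
#' or any ratio-vs-time table.
#' @param t times (hr).
#' @param value measured widths/thicknesses/areas (positive).
#' @param region region label.
#' @return A `region_series`.
#' @export
region_series <- function(t, value, region = "region") {
  if (any(value <= 0)) stop_validation("series values must be positive")
  o <- order(t)
  structure(data.frame(region = region, t = t[o], width = value[o],
                       ratio = value[o] / value[o][1]),
            initial_width = stats::setNames(value[o][1], region),
            class = c("region_series", "data.frame"))
}

#' Convergence rate as percent of initial extent per hour
#'
#' OLS slope of the ratio series versus time, times -100, so that positive
#' rates mean convergence (shrinkage). The "% per hour" convention is linear
#' in the ratio `W_t/W_i` (fraction of the initial width per hour), matching
#' how convergence is plotted and reported.
#'
#' @param series a `region_series`.
#' @param window `c(t_start, t_end)` (hr); default the full span.
#' @param region which region, when the series has several; default: all,
#'   returned as a data frame.
#' @param conf confidence level for the interval.
#' @return For one region, an object of class `convergence_rate` (rate,
#'   standard error, CI, n); for several, a data frame with one row each.
#' @export
estimate_rate <- function(series, window = NULL, region = NULL, conf = 0.95) {
  stopifnot(inherits(series, "region_series"))
  regs <- unique(series$region)
  if (is.null(region) && length(regs) > 1) {
    out <- do.call(rbind, lapply(regs, function(r) {
      er <- estimate_rate(series, window, region = r, conf = conf)
      data.frame(region = r, rate = er$rate, se = er$se,
                 lo = er$ci[1], hi = er$ci[2], n = er$n)
    }))
    return(out)
  }
  region <- region %||% regs[1]
  d <- series[series$region == region, ]
  if (!is.null(window)) d <- d[d$t >= window[1] & d$t <= window[2], ]
  if (nrow(d) < 3)
    stop_validation("rate estimation needs >= 3 timepoints in the window (got %d)",
                    nrow(d))
  fit <- stats::lm.fit(cbind(1, d$t), d$ratio)
  sl <- fit$coefficients[[2]]
  se <- sqrt(sum(fit$residuals^2) / (nrow(d) - 2) / sum((d$t - mean(d$t))^2))
  tcrit <- stats::qt(1 - (1 - conf) / 2, df = nrow(d) - 2)
  structure(list(region = region, rate = -100 * sl, se = 100 * se,
                 ci = c(-100 * sl - tcrit * 100 * se,
                        -100 * sl + tcrit * 100 * se),
                 n = nrow(d), window = range(d$t)),
            class = "convergence_rate")
}

#' @export
print.convergence_rate <- function(x, ...) {
  cat(sprintf("Convergence rate, region '%s': %.2f %%/hr (SE %.2f, %d points, t in [%.2f, %.2f] hr)\n",
              x$region, x$rate, x$se, x$n, x$window[1], x$window[2]))
  invisible(x)
}

#' Detect a change in convergence rate
#'
#' Two-segment continuous piecewise-linear fit of the ratio series versus
#' time, with the breakpoint found by exhaustive search over interior sample
#' times (minimizing total squared error). The two-segment model is kept
#' only if it improves on a single line by an F-criterion (2 extra
#' parameters: the hinge slope and the breakpoint); otherwise "no
#' changepoint" is reported. Degenerate perfect-line series also report no
#' changepoint.
#'
#' @param series a `region_series`.
#' @param region which region (default the first).
#' @param alpha significance level of the F-criterion.
#' @param min_seg minimum points per segment.
#' @return Object of class `rate_change`: `has_changepoint`, `changepoint`
#'   (hr), `rate_before`, `rate_after` (%/hr), `p_value`, `rss`.
#' @export
detect_rate_change <- function(series, region = NULL, alpha = 0.05, min_seg = 3) {
  stopifnot(inherits(series, "region_series"))
  region <- region %||% unique(series$region)[1]
  d <- series[series$region == region, ]
  t <- d$t; y <- d$ratio; n <- length(t)
  if (n < 2 * min_seg)
    stop_validation("changepoint detection needs >= %d points", 2 * min_seg)
  X0 <- cbind(1, t)
  f0 <- stats::lm.fit(X0, y)
  rss0 <- sum(f0$residuals^2)
  cand <- t[seq(min_seg, n - min_seg)]
  cand <- unique(cand)
  best <- list(rss = Inf, cp = NA_real_, coef = NULL)
  for (cp in cand) {
    X <- cbind(1, t, pmax(t - cp, 0))
    f1 <- stats::lm.fit(X, y)
    rss <- sum(f1$residuals^2)
    if (rss < best$rss) best <- list(rss = rss, cp = cp, coef = f1$coefficients)
  }
  scale2 <- mean(y^2)
  if (rss0 <= 1e-20 * n * scale2) {        # already a perfect single line
    return(structure(list(has_changepoint = FALSE, changepoint = NA_real_,
                          rate_before = -100 * unname(f0$coefficients[[2]]),
                          rate_after = -100 * unname(f0$coefficients[[2]]),
                          p_value = 1, rss = rss0, region = region),
                     class = "rate_change"))
  }
  Fstat <- ((rss0 - best$rss) / 2) / (best$rss / (n - 4))
  p <- stats::pf(Fstat, 2, n - 4, lower.tail = FALSE)
  if (!is.finite(Fstat)) { Fstat <- Inf; p <- 0 }   # perfect two-segment fit
  has <- p < alpha
  rb <- -100 * unname(best$coef[2])
  ra <- -100 * unname(best$coef[2] + best$coef[3])
  structure(list(has_changepoint = has,
                 changepoint = if (has) best$cp else NA_real_,
                 rate_before = if (has) rb else -100 * f0$coefficients[[2]],
                 rate_after = if (has) ra else -100 * f0$coefficients[[2]],
                 p_value = p, rss = if (has) best$rss else rss0,
                 region = region),
            class = "rate_change")
}

#' @export
print.rate_change <- function(x, ...) {
  if (x$has_changepoint) {
    cat(sprintf(
      "Rate change, region '%s': breakpoint at %.2f hr; %.2f -> %.2f %%/hr (p = %.3g)\n",
      x$region, x$changepoint, x$rate_before, x$rate_after, x$p_value))
  } else {
    cat(sprintf("Region '%s': no changepoint (single rate %.2f %%/hr, p = %.3g)\n",
                x$region, x$rate_before, x$p_value))
  }
  invisible(x)
}

#' Spherical-geometry correction of projected areas
#'
#' Corrects an apparent (2-D projected) area on a spherical embryo for
#' curvature, for regions concentric about the viewing axis. A polar cap of
#' projected radius `r_proj` on a sphere of radius `R` subtends
#' \eqn{\theta = \arcsin(r_{proj}/R)} and has true area
#' \eqn{2\pi R^2 (1 - \cos\theta)}; annuli are differences of caps. The
#' correction factor (true/projected) is 1 in the flat limit and exactly 2
#' for the full hemisphere.
#'
#' @param R embryo radius (same length unit as `r_proj`).
#' @param r_proj projected cap radius, `0 <= r_proj <= R`.
#' @return List with `area_true`, `area_proj` (\eqn{\pi r_{proj}^2}) and
#'   `factor = area_true/area_proj`.
#' @export
spherical_cap_area <- function(R, r_proj) {
  if (any(r_proj < 0)) stop_validation("'r_proj' must be >= 0")
  if (any(r_proj > R)) stop_validation("'r_proj' exceeds the sphere radius R")
  theta <- asin(pmin(r_proj / R, 1))
  a_true <- 2 * pi * R^2 * (1 - cos(theta))
  a_proj <- pi * r_proj^2
  list(area_true = a_true, area_proj = a_proj,
       factor = ifelse(r_proj > 0, a_true / a_proj, 1))
}

#' @rdname spherical_cap_area
#' @param r_in,r_out projected radii bounding an annulus about the viewing
#'   axis.
#' @export
spherical_annulus_area <- function(R, r_in, r_out) {
  if (any(r_out < r_in)) stop_validation("'r_out' must be >= 'r_in'")
  spherical_cap_area(R, r_out)$area_true - spherical_cap_area(R, r_in)$area_true
}

#' Blastopore closure curve
#'
#' The closure metric is the projected blastopore area over the projected
#' whole-embryo area, \eqn{A_{bp}/A_{we}}, per timepoint; closure is scored
#' when the ratio first reaches a configured floor (linear interpolation
#' between samples).
#'
#' @param t times (hr).
#' @param A_bp projected blastopore areas, `0 <= A_bp <= A_we`.
#' @param A_we projected whole-embryo areas, > 0.
#' @param closure_floor ratio at which the blastopore is scored closed.
#' @return Object of class `closure_curve`: data frame `t, ratio` with
#'   attributes `closure_time` (NA if the floor is not reached) and
#'   `closure_floor`.
#' @export
blastopore_closure <- function(t, A_bp, A_we, closure_floor = 0.01) {
  if (any(A_we <= 0)) stop_validation("'A_we' must be > 0")
  if (any(A_bp < 0)) stop_validation("'A_bp' must be >= 0")
  if (any(A_bp > A_we)) stop_validation("blastopore area exceeds whole-embryo area")
  o <- order(t)
  ratio <- (A_bp / A_we)[o]; t <- t[o]
  ct <- NA_real_
  below <- which(ratio <= closure_floor)
  if (length(below)) {
    i <- below[1]
    ct <- if (i == 1) t[1]
          else stats::approx(ratio[(i - 1):i], t[(i - 1):i], xout = closure_floor)$y
  }
  structure(data.frame(t = t, ratio = ratio),
            closure_time = ct, closure_floor = closure_floor,
            class = c("closure_curve", "data.frame"))
}

#' Cell-shape metrics from traced outlines
#'
#' Per cell and timepoint: polygon perimeter and area, circularity
#' \eqn{4\pi A/P^2}, length-width ratio from the second-moment best-fit
#' ellipse, centroid movement rate between consecutive frames, and
#' perimeter change rate. Self-intersecting outlines are rejected and
#' logged.
#'
#' @param outlines data frame with columns `cell`, `t` (minutes), `x`, `y`
#'   (vertices in traced order, one closed outline per cell per time).
#' @return Data frame with one row per (cell, t): `perimeter`, `area`,
#'   `circularity`, `length_width_ratio`, `centroid_x`, `centroid_y`,
#'   `centroid_speed` (length/min, NA at the first frame), and
#'   `perimeter_change` (length/min).
#' @export
cell_shape_metrics <- function(outlines) {
  need <- c("cell", "t", "x", "y")
  if (!all(need %in% names(outlines)))
    stop_validation("outlines need columns: %s", paste(need, collapse = ", "))
  res <- list()
  for (cell in unique(outlines$cell)) {
    dcell <- outlines[outlines$cell == cell, ]
    ts <- sort(unique(dcell$t))
    rows <- lapply(ts, function(tt) {
      o <- dcell[dcell$t == tt, ]
      if (nrow(o) < 3) return(NULL)
      if (polyline_self_intersects(o$x, o$y, closed = TRUE)) {
        message(sprintf("cell_shape_metrics: cell '%s' t=%.3g: self-intersecting outline rejected",
                        cell, tt))
        return(NULL)
      }
      mom <- polygon_moments(o$x, o$y)
      A <- abs(mom$A)
      P <- polygon_perimeter(o$x, o$y, closed = TRUE)
      ev <- eigen(matrix(c(mom$Ixx, mom$Ixy, mom$Ixy, mom$Iyy), 2, 2),
                  symmetric = TRUE)$values
      lwr <- sqrt(max(ev) / max(min(ev), .Machine$double.xmin))
      data.frame(cell = cell, t = tt, perimeter = P, area = A,
                 circularity = 4 * pi * A / P^2,
                 length_width_ratio = lwr,
                 centroid_x = mom$cx, centroid_y = mom$cy)
    })
    rows <- do.call(rbind, rows)
    if (is.null(rows)) next
    n <- nrow(rows)
    dtm <- c(NA, diff(rows$t))
    rows$centroid_speed <- c(NA, sqrt(diff(rows$centroid_x)^2 +
                                        diff(rows$centroid_y)^2)) / dtm
    rows$perimeter_change <- c(NA, diff(rows$perimeter)) / dtm
    res[[cell]] <- rows
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Group means, SEM, and unpaired two-tailed t test
#'
#' The reporting convention of the measurement stack: arithmetic means with
#' SEM error bars, compared by an unpaired two-tailed t test. The classic
#' pooled-variance form is computed in-package (with a Welch option), so it
#' can be cross-checked against a reference implementation.
#'
#' @param values numeric measurements.
#' @param groups group labels, same length.
#' @param welch use the Welch (unequal-variance) form? Default `FALSE`
#'   (classic pooled unpaired t).
#' @return Object of class `group_summary`: `summary` (per-group n, mean,
#'   sd, sem; sem is `NA` with a flag when n < 2) and, for exactly two
#'   groups, `t`, `df`, `p_value`.
#' @export
summarize_groups <- function(values, groups, welch = FALSE) {
  if (length(values) != length(groups))
    stop_validation("'values' and 'groups' must have equal length")
  groups <- factor(groups)
  agg <- do.call(rbind, lapply(levels(groups), function(gl) {
    v <- values[groups == gl]
    data.frame(group = gl, n = length(v), mean = mean(v),
               sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
               sem = if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_)
  }))
  flags <- if (any(agg$n < 2)) "sem_undefined_for_n_lt_2" else character(0)
  tt <- df <- p <- NA_real_
  if (nlevels(groups) == 2 && all(agg$n >= 2)) {
    v1 <- values[groups == levels(groups)[1]]
    v2 <- values[groups == levels(groups)[2]]
    n1 <- length(v1); n2 <- length(v2)
    m1 <- mean(v1); m2 <- mean(v2)
    if (welch) {
      se2 <- stats::var(v1) / n1 + stats::var(v2) / n2
      df <- se2^2 / ((stats::var(v1) / n1)^2 / (n1 - 1) +
                       (stats::var(v2) / n2)^2 / (n2 - 1))
      se <- sqrt(se2)
    } else {
      sp2 <- ((n1 - 1) * stats::var(v1) + (n2 - 1) * stats::var(v2)) / (n1 + n2 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      df <- n1 + n2 - 2
    }
    tt <- if (m1 == m2) 0 else if (se == 0) sign(m1 - m2) * Inf else (m1 - m2) / se
    p <- 2 * stats::pt(-abs(tt), df)
  }
  structure(list(summary = agg, t = tt, df = df, p_value = p,
                 welch = welch, flags = flags),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  if (!is.na(x$t))
    cat(sprintf("%s t = %.4g, df = %.4g, two-tailed p = %.4g\n",
                if (x$welch) "Welch" else "Pooled", x$t, x$df, x$p_value))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
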