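# Contour extraction: turn profile images (or small confocal stacks) into
# QC'd aggregate outlines for the fitting module.

#' Maximum-intensity projection of a confocal stack
#'
#' Projects a 3-D stack to 2-D by taking the per-pixel maximum over slices
#' (profile imaging of labeled aggregates typically projects two to six
#' confocal slices). A 2-D input is returned unchanged with a note.
#'
#' @param stack an [image_stack()].
#' @return A 2-D [image_stack()].
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  if (length(d) == 2L) {
    message("max_project: input is already 2-D; returned unchanged")
    return(stack)
  }
  proj <- apply(stack$data, c(1, 2), max)
  out <- image_stack(proj, stack$pixel_scale, slice_spacing = NA_real_,
                     channel = stack$channel)
  attr(out, "truth") <- attr(stack, "truth")
  out
}

# Canny edge detector on a 2-D matrix: Gaussian smoothing, Sobel gradients,
# non-maximum suppression along the quantized gradient direction, and
# hysteresis linking (weak-edge components are kept only when they touch a
# strong pixel). Thresholds default to gradient-magnitude percentiles.
# Returns list(edges = logical matrix, magnitude = smoothed gradient magnitude).
canny_edges <- function(m, smoothing_sd = 2, thresholds = NULL,
                        percentiles = c(0.5, 0.9)) {
  if (smoothing_sd > 0) m <- EBImage::gblur(m, sigma = smoothing_sd)
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)  # d/d(dim1)
  gx <- EBImage::filter2(m, sx)
  gy <- EBImage::filter2(m, t(sx))
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx)
  # quantize direction to 0, 45, 90, 135 degrees
  sector <- (round(ang / (pi / 4)) %% 4)
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(a, di, dj) {
    out <- matrix(0, nr, nc)
    i1 <- max(1, 1 + di):min(nr, nr + di)
    j1 <- max(1, 1 + dj):min(nc, nc + dj)
    out[i1, j1] <- a[i1 - di, j1 - dj]
    out
  }
  nms <- matrix(FALSE, nr, nc)
  steps <- list(`0` = c(1, 0), `1` = c(1, 1), `2` = c(0, 1), `3` = c(-1, 1))
  for (k in 0:3) {
    st <- steps[[k + 1]]
    sel <- sector == k
    keep <- mag >= shift(mag, st[1], st[2]) & mag >= shift(mag, -st[1], -st[2])
    nms <- nms | (sel & keep)
  }
  nzmag <- mag[mag > 0]
  if (is.null(thresholds)) {
    if (length(nzmag) == 0) return(list(edges = matrix(FALSE, nr, nc), magnitude = mag))
    thresholds <- stats::quantile(nzmag, percentiles, names = FALSE)
  }
  weak <- nms & mag >= thresholds[1]
  strong <- nms & mag >= thresholds[2]
  if (!any(strong)) return(list(edges = matrix(FALSE, nr, nc), magnitude = mag))
  lab <- EBImage::bwlabel(weak)
  keep_ids <- unique(lab[strong])
  keep_ids <- keep_ids[keep_ids > 0]
  list(edges = matrix(lab %in% keep_ids, nr, nc), magnitude = mag)
}

# Parabolic subpixel refinement: slide each ordered contour point along its
# local outward normal to the interpolated gradient-magnitude maximum.
refine_subpixel <- function(px, pz, mag) {
  n <- length(px)
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  tx <- px[nxt] - px[prv]; tz <- pz[nxt] - pz[prv]
  len <- sqrt(tx^2 + tz^2); len[len == 0] <- 1
  nx <- -tz / len; nz <- tx / len
  bilin <- function(x, z) {
    i0 <- pmin(pmax(floor(x), 1L), nrow(mag) - 1L)
    j0 <- pmin(pmax(floor(z), 1L), ncol(mag) - 1L)
    fx <- x - i0; fz <- z - j0
    mag[cbind(i0, j0)] * (1 - fx) * (1 - fz) +
      mag[cbind(i0 + 1L, j0)] * fx * (1 - fz) +
      mag[cbind(i0, j0 + 1L)] * (1 - fx) * fz +
      mag[cbind(i0 + 1L, j0 + 1L)] * fx * fz
  }
  m0 <- bilin(px, pz)
  mp <- bilin(px + nx, pz + nz)
  mm <- bilin(px - nx, pz - nz)
  den <- mp - 2 * m0 + mm
  delta <- ifelse(abs(den) > .Machine$double.eps, 0.5 * (mm - mp) / den, 0)
  delta <- pmin(pmax(delta, -1), 1)
  list(x = px + delta * nx, z = pz + delta * nz)
}

#' Extract a QC'd aggregate contour from a profile image
#'
#' Pipeline: Gaussian smoothing, Canny edge detection, hysteresis linking,
#' selection of the largest closed edge region, ordered boundary tracing,
#' and subpixel refinement of each boundary point along its normal to the
#' gradient-magnitude maximum. The result is an ordered, apex-centered
#' contour in physical units with QC metrics attached. Images are meant to
#' be inspected: use [inspection_overlay()] to view the extraction on top of
#' the image.
#'
#' @param image an [image_stack()]; 3-D stacks are max-projected first.
#' @param smoothing_sd Gaussian smoothing SD (pixels).
#' @param canny_thresholds optional `c(low, high)` gradient thresholds;
#'   default is an automatic percentile rule (50th/90th percentile of the
#'   nonzero gradient magnitude).
#' @param qc_thresholds passed to [qc_contour()].
#' @return An [observed_contour()] ordered counterclockwise starting at the
#'   apex-most (minimum-z) point, translated so the apex is at the origin,
#'   with a `qc` attribute.
#' @export
extract_contour <- function(image, smoothing_sd = 2, canny_thresholds = NULL,
                            qc_thresholds = list()) {
  stopifnot(inherits(image, "image_stack"))
  if (length(dim(image$data)) == 3L) image <- max_project(image)
  m <- image$data
  ce <- canny_edges(m, smoothing_sd, canny_thresholds)
  if (!any(ce$edges)) stop("contour extraction failed: no edges found", call. = FALSE)
  filled <- EBImage::fillHull(EBImage::Image(ce$edges * 1))
  lab <- EBImage::bwlabel(filled)
  sizes <- tabulate(lab[lab > 0])
  if (length(sizes) == 0)
    stop("contour extraction failed: no closed contour found", call. = FALSE)
  best <- which.max(sizes)
  n_edge <- sum(ce$edges)
  if (sizes[best] < 2 * n_edge)
    stop("contour extraction failed: edges do not close into a region", call. = FALSE)
  if (length(sizes) > 1)
    message(sprintf("extract_contour: %d candidate regions; largest (area %d px) chosen",
                    length(sizes), sizes[best]))
  oc <- EBImage::ocontour(EBImage::Image(lab == best))[[1]]
  px <- oc[, 1] + 1; pz <- oc[, 2] + 1      # ocontour is 0-based [ix, iz]
  ref <- refine_subpixel(px, pz, ce$magnitude)
  # light smoothing of the traced boundary (circular moving average)
  sm <- function(v, w = 5) {
    n <- length(v); half <- w %/% 2
    vv <- c(v[(n - half + 1):n], v, v[1:half])
    stats::filter(vv, rep(1 / w, w))[(half + 1):(half + n)]
  }
  x <- as.numeric(sm(ref$x)); z <- as.numeric(sm(ref$z))
  # counterclockwise in (x, z) with z down == negative shoelace in standard
  # orientation; enforce a consistent traversal then start at the apex.
  if (polygon_area(x, z) < 0) { x <- rev(x); z <- rev(z) }
  i0 <- which.min(z)
  idx <- c(i0:length(x), seq_len(i0 - 1L))
  x <- x[idx]; z <- z[idx]
  ps <- image$pixel_scale
  xm <- (x - x[1]) * ps
  zm <- (z - min(z)) * ps
  cont <- observed_contour(data.frame(x = xm, z = zm), pixel_scale = ps,
                           source = list(kind = "extracted",
                                         frame_px = dim(m),
                                         apex_px = c(x[1], min(z))),
                           closed = TRUE)
  # QC judges the full closed silhouette ...
  qc <- do.call(qc_contour, c(list(cont), qc_thresholds))
  # ... but the sessile aggregate rests on a substrate: points on the flat
  # base chord belong to the support, not the free surface, and would bias a
  # drop-shape fit. Trim the band within ~2 px of maximum depth and record
  # the substrate line.
  band <- 2 * ps
  surf <- zm < max(zm) - band
  if (sum(surf) >= 20) {
    cont <- observed_contour(data.frame(x = xm[surf], z = zm[surf]),
                             pixel_scale = ps,
                             source = list(kind = "extracted",
                                           frame_px = dim(m),
                                           apex_px = c(x[1], min(z)),
                                           substrate_line = max(zm)),
                             closed = TRUE)
  }
  attr(cont, "qc") <- qc
  attr(cont, "truth") <- attr(image, "truth")
  cont
}

#' Contour quality control
#'
#' Operationalizes the rejection of aggregates too irregular for drop-shape
#' analysis: computes circularity \eqn{4\pi A/P^2}, convexity deficiency
#' \eqn{1 - A/A_{hull}}, and closedness/simplicity, and accepts the contour
#' when circularity >= `c_min` and convexity deficiency <= `d_max`. The
#' default thresholds (0.6, 0.15) are generous enough to pass strongly
#' gravity-flattened drops while rejecting ragged or lobed outlines.
#'
#' @param contour an [observed_contour()].
#' @param c_min minimum circularity.
#' @param d_max maximum convexity deficiency.
#' @return Object of class `contour_qc`: list with `circularity`,
#'   `convexity_deficiency`, `closedness`, `irregularity_score` (composite:
#'   `(1 - circularity) + convexity_deficiency`), `accepted`.
#' @export
qc_contour <- function(contour, c_min = 0.6, d_max = 0.15) {
  x <- contour$x; z <- contour$z
  closed <- isTRUE(attr(contour, "closed")) ||
    sqrt((x[1] - x[length(x)])^2 + (z[1] - z[length(z)])^2) <
      0.05 * polygon_perimeter(x, z, closed = FALSE)
  simple <- !polyline_self_intersects(x, z, closed = TRUE)
  A <- abs(polygon_area(x, z))
  P <- polygon_perimeter(x, z, closed = TRUE)
  circ <- 4 * pi * A / P^2
  hull <- grDevices::chull(x, z)
  Ah <- abs(polygon_area(x[hull], z[hull]))
  cd <- max(0, 1 - A / Ah)
  structure(list(circularity = circ, convexity_deficiency = cd,
                 closedness = closed, simple = simple,
                 irregularity_score = (1 - circ) + cd,
                 accepted = closed && simple && circ >= c_min && cd <= d_max,
                 c_min = c_min, d_max = d_max),
            class = "contour_qc")
}

#' @export
print.contour_qc <- function(x, ...) {
  cat("Contour QC\n")
  cat(sprintf("  circularity          : %.4f (min %.2f)\n", x$circularity, x$c_min))
  cat(sprintf("  convexity deficiency : %.4f (max %.2f)\n", x$convexity_deficiency, x$d_max))
  cat(sprintf("  closed / simple      : %s / %s\n", x$closedness, x$simple))
  cat(sprintf("  accepted             : %s\n", x$accepted))
  invisible(x)
}

#' Inspection overlay of an extraction
#'
#' Plots the image with the extracted contour superimposed, for the manual
#' inspection step of the extraction protocol.
#'
#' @param image an [image_stack()].
#' @param contour the [observed_contour()] extracted from it.
#' @param ... passed to [graphics::image()].
#' @export
inspection_overlay <- function(image, contour, ...) {
  m <- if (length(dim(image$data)) == 3L) apply(image$data, c(1, 2), max) else image$data
  graphics::image(x = seq_len(nrow(m)) - 0.5, y = seq_len(ncol(m)) - 0.5,
                  z = m[, ncol(m):1],
                  col = grDevices::gray.colors(64, 0, 1), asp = 1,
                  xlab = "x (px)", ylab = "z (px, up)", ...)
  src <- attr(contour, "source")
  apex <- src$apex_px %||% c(0, 0)
  px <- contour$x / attr(contour, "pixel_scale") + apex[1]
  pz <- contour$z / attr(contour, "pixel_scale") + apex[2]
  graphics::lines(px, ncol(m) - pz, col = "red", lwd = 2)
  invisible(NULL)
}
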