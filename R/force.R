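# Interfacial-tension -> tissue-force model: tension acting over the traced
# deep/superficial interface contour yields the convergence/thickening force,
# F = sigma_em * L_i.

#' Interface polyline
#'
#' An ordered trace of the boundary between deep mesodermal tissue and the
#' surrounding tissue in an explant cross-section. Duplicate consecutive
#' points are collapsed with a message.
#'
#' @param points data frame or matrix with columns `x`, `y` (m).
#' @param closed include the closing segment in the length?
#' @param pairing tissue pairing label (e.g. "deep mesoderm / epithelium").
#' @return Object of class `interface_polyline` with attribute `L_i`, the
#'   contour length (m).
#' @export
interface_polyline <- function(points, closed = FALSE, pairing = "") {
  points <- as.data.frame(points)
  if (ncol(points) >= 2 && !all(c("x", "y") %in% names(points)))
    names(points)[1:2] <- c("x", "y")
  dup <- c(FALSE, diff(points$x) == 0 & diff(points$y) == 0)
  if (any(dup)) {
    message(sprintf("interface_polyline: %d duplicate consecutive point(s) collapsed",
                    sum(dup)))
    points <- points[!dup, ]
  }
  if (nrow(points) < 2) stop_validation("an interface needs >= 2 distinct points")
  structure(points[, c("x", "y")],
            closed = closed, pairing = pairing,
            L_i = polygon_perimeter(points$x, points$y, closed = closed),
            class = c("interface_polyline", "data.frame"))
}

#' Interface contour length
#'
#' Sum of Euclidean segment lengths along the traced interface; the closing
#' segment is included iff the polyline is closed.
#'
#' @param poly an [interface_polyline()], or anything accepted by its
#'   constructor.
#' @param closed used when `poly` is raw points.
#' @return Length (m).
#' @examples
#' interface_length(data.frame(x = c(0, 3, 3), y = c(0, 0, 4)))  # 7
#' @export
interface_length <- function(poly, closed = FALSE) {
  if (!inherits(poly, "interface_polyline"))
    poly <- interface_polyline(poly, closed = closed)
  attr(poly, "L_i")
}

#' Convergence/thickening force predicted from interfacial tension
#'
#' The scalar line-tension model: an interfacial tension `sigma_em` acting
#' over the whole interface contour length `L_i` produces a force
#' \eqn{F = \sigma_{em} L_i} along the explant's long axis. At the measured
#' tension scale (e.g. 0.22 mN/m over a 1.2 mm interface) this predicts
#' forces of a few tenths of a micronewton, the scale observed in
#' convergence- and thickening-force assays.
#'
#' @param sigma_em interfacial tension (N/m), >= 0.
#' @param L_i interface contour length (m), >= 0, or an
#'   [interface_polyline()].
#' @return Object of class `force_prediction`: `sigma_em`, `L_i`, `force`
#'   (N), `force_uN` (rounded to two decimals, the reporting granularity).
#' @examples
#' predict_force(0.22e-3, 1.2e-3)  # 0.26 uN
#' @export
predict_force <- function(sigma_em, L_i) {
  if (inherits(L_i, "interface_polyline")) L_i <- attr(L_i, "L_i")
  if (!is.numeric(sigma_em) || any(sigma_em < 0))
    stop_validation("'sigma_em' must be >= 0")
  if (!is.numeric(L_i) || any(L_i < 0)) stop_validation("'L_i' must be >= 0")
  f <- sigma_em * L_i
  structure(list(sigma_em = sigma_em, L_i = L_i, force = f,
                 force_uN = round(1e6 * f, 2)),
            class = "force_prediction")
}

#' @export
print.force_prediction <- function(x, ...) {
  cat(sprintf("Predicted force: F = sigma * L = %.4g mN/m x %.4g mm = %.2f uN\n",
              1e3 * x$sigma_em, 1e3 * x$L_i, x$force_uN))
  invisible(x)
}

#' Compare a predicted force with a measured one
#'
#' Reports the predicted/measured ratio and absolute difference, carrying
#' the measured uncertainty through; no pass/fail verdict is attached. A
#' zero measured force with a nonzero prediction gives an undefined ratio
#' with a flag.
#'
#' @param predicted a [predict_force()] result or a force in N.
#' @param measured measured force (N).
#' @param measured_sem SEM of the measured force (N), optional.
#' @return Object of class `force_comparison`.
#' @export
compare_forces <- function(predicted, measured, measured_sem = NA_real_) {
  fp <- if (inherits(predicted, "force_prediction")) predicted$force else predicted
  flags <- character(0)
  if (measured == 0 && fp != 0) {
    ratio <- NA_real_
    flags <- "ratio_undefined_measured_zero"
  } else if (measured == 0 && fp == 0) {
    ratio <- 1
  } else {
    ratio <- fp / measured
  }
  ratio_sem <- if (!is.na(measured_sem) && measured != 0)
    abs(ratio) * measured_sem / abs(measured) else NA_real_
  structure(list(predicted = fp, measured = measured,
                 measured_sem = measured_sem,
                 ratio = ratio, ratio_sem = ratio_sem,
                 difference = fp - measured, flags = flags),
            class = "force_comparison")
}

#' @export
print.force_comparison <- function(x, ...) {
  cat(sprintf("Predicted %.2f uN vs measured %.2f uN", 1e6 * x$predicted,
              1e6 * x$measured))
  if (!is.na(x$measured_sem)) cat(sprintf(" (SEM %.2f uN)", 1e6 * x$measured_sem))
  cat("\n")
  if (is.na(x$ratio)) {
    cat("  ratio undefined (measured force is zero)\n")
  } else {
    cat(sprintf("  ratio = %.3g%s, difference = %.2f uN\n", x$ratio,
                if (!is.na(x$ratio_sem)) sprintf(" (SEM %.2g)", x$ratio_sem) else "",
                1e6 * x$difference))
  }
  invisible(x)
}
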