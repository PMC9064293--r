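# Internal geometry and plumbing helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded at `seed`, then restores the caller's RNG
#' state, so generators are deterministic per seed without disturbing the
#' session stream.
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Signed area of a polygon (positive = counterclockwise); vertices not repeated.
polygon_area <- function(x, y) {
  pracma::polyarea(x, y)
}

polygon_perimeter <- function(x, y, closed = TRUE) {
  dx <- diff(x); dy <- diff(y)
  p <- sum(sqrt(dx^2 + dy^2))
  if (closed) p <- p + sqrt((x[1] - x[length(x)])^2 + (y[1] - y[length(y)])^2)
  p
}

# Exact polygon centroid and second central moments (about the centroid),
# by the standard shoelace-weighted formulas. Returns list(A, cx, cy, Ixx, Iyy, Ixy)
# where the moments are area-normalized (i.e. the covariance of the uniform
# lamina), so eigenvalues relate to ellipse semi-axes by lambda = axis^2 / 4.
polygon_moments <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  A <- sum(cr) / 2
  cx <- sum((x + x[j]) * cr) / (6 * A)
  cy <- sum((y + y[j]) * cr) / (6 * A)
  x0 <- x - cx; y0 <- y - cy
  cr0 <- x0 * y0[j] - x0[j] * y0
  Ixx <- sum((x0^2 + x0 * x0[j] + x0[j]^2) * cr0) / 12
  Iyy <- sum((y0^2 + y0 * y0[j] + y0[j]^2) * cr0) / 12
  Ixy <- sum((x0 * y0[j] + 2 * x0 * y0 + 2 * x0[j] * y0[j] + x0[j] * y0) * cr0) / 24
  list(A = A, cx = cx, cy = cy, Ixx = Ixx / A, Iyy = Iyy / A, Ixy = Ixy / A)
}

# Does the closed polyline (x, y) intersect itself? Brute-force segment pair
# test, vectorized over pairs; adjacent segments (sharing a vertex) are skipped.
polyline_self_intersects <- function(x, y, closed = TRUE) {
  n <- length(x)
  if (n < 4) return(FALSE)
  # a vertex visited twice (non-consecutively) is a self-contact
  if (anyDuplicated(cbind(x, y)) &&
      any(duplicated(cbind(x, y)) & !(c(FALSE, diff(x) == 0 & diff(y) == 0))))
    return(TRUE)
  if (closed) { x <- c(x, x[1]); y <- c(y, y[1]) }
  m <- length(x) - 1L        # number of segments
  ax <- x[seq_len(m)]; ay <- y[seq_len(m)]
  bx <- x[seq_len(m) + 1L]; by <- y[seq_len(m) + 1L]
  ij <- which(outer(seq_len(m), seq_len(m), function(i, j) j > i + 1L), arr.ind = TRUE)
  if (closed) ij <- ij[!(ij[, 1] == 1L & ij[, 2] == m), , drop = FALSE]
  if (nrow(ij) == 0) return(FALSE)
  i <- ij[, 1]; j <- ij[, 2]
  d1x <- bx[i] - ax[i]; d1y <- by[i] - ay[i]
  d2x <- bx[j] - ax[j]; d2y <- by[j] - ay[j]
  ex <- ax[j] - ax[i]; ey <- ay[j] - ay[i]
  den <- d1x * d2y - d1y * d2x
  t1 <- (ex * d2y - ey * d2x) / den
  t2 <- (ex * d1y - ey * d1x) / den
  # closed parameter window: non-adjacent segments of a simple polygon never
  # touch, so endpoint contact between them is genuine self-contact
  eps <- 1e-12
  hit <- is.finite(t1) & is.finite(t2) &
    t1 > -eps & t1 < 1 + eps & t2 > -eps & t2 < 1 + eps
  any(hit)
}

# Least-squares (Kasa) circle fit: returns center (cx, cy) and radius r.
fit_circle <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(A, b)
  cx <- sol[1]; cy <- sol[2]
  r <- sqrt(sol[3] + cx^2 + cy^2)
  list(cx = cx, cy = cy, r = r)
}

# Minimum distances from query points (px, py) to a polyline (vx, vy).
# Nearest-vertex search first, then exact point-to-segment distance on the
# segments adjacent to the nearest vertex (adequate for densely sampled curves).
polyline_min_dist <- function(px, py, vx, vy) {
  d2 <- outer(px, vx, "-")^2 + outer(py, vy, "-")^2
  idx <- max.col(-d2, ties.method = "first")
  nv <- length(vx)
  best <- d2[cbind(seq_along(px), idx)]
  for (off in c(-1L, 0L)) {
    i1 <- idx + off
    ok <- i1 >= 1L & i1 < nv
    if (!any(ok)) next
    i1k <- i1[ok]
    axp <- vx[i1k]; ayp <- vy[i1k]
    dxs <- vx[i1k + 1L] - axp; dys <- vy[i1k + 1L] - ayp
    len2 <- dxs^2 + dys^2
    tt <- ((px[ok] - axp) * dxs + (py[ok] - ayp) * dys) / pmax(len2, .Machine$double.xmin)
    tt <- pmin(pmax(tt, 0), 1)
    qx <- axp + tt * dxs; qy <- ayp + tt * dys
    dd <- (px[ok] - qx)^2 + (py[ok] - qy)^2
    best[ok] <- pmin(best[ok], dd)
  }
  sqrt(best)
}

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
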