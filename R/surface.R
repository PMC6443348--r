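# Thin-plate spline model of the air-water interface fitted through
# particle centers.
#
# f(x,y) = a0 + ax*x + ay*y + sum_i w_i U(r_i),  U(r) = r^2 log r, U(0) = 0,
# subject to the side conditions sum w = sum w*x = sum w*y = 0. lambda >= 0
# is added to the kernel diagonal (lambda = 0: exact interpolation).
# Coordinates are centered on their centroid internally before the system is
# assembled, which makes the fit exactly invariant under in-plane
# translation; the interpolant itself is translation/rotation invariant, so
# this changes nothing mathematically.

tps_kernel <- function(r) {
  u <- numeric(length(r))
  pos <- r > 0
  u[pos] <- r[pos]^2 * log(r[pos])
  u
}

#' Fit a thin-plate spline interface through particle centers
#'
#' Solves the standard thin-plate system through 3D points treated as a
#' height field z = f(x, y). With `lambda = 0` (default) every control point
#' is interpolated exactly; `lambda > 0` smooths. The bordered linear system
#' is solved by the null-space (QR) method: the spline weights are sought in
#' the orthogonal complement of the polynomial space, which enforces the
#' side conditions exactly.
#'
#' @param points N x 3 matrix of particle centers (Angstrom), N >= 3, with a
#'   non-collinear (x, y) footprint. Points whose (x, y) coincide within
#'   1e-6 Angstrom are merged by averaging their z first.
#' @param lambda smoothing parameter >= 0 added to the kernel diagonal.
#' @param side which meniscus this surface is: `"upper"` (air above, normals
#'   point +z) or `"lower"` (air below, normals point -z). Explicit metadata,
#'   never inferred, because a silent sign flip would invert the whole
#'   displacement-angle distribution.
#' @return an object of class `tps_surface` with fields `control_xy`,
#'   `control_z`, `weights`, `affine` (a0, ax, ay in centered coordinates),
#'   `centroid`, `lambda`, `side`.
#' @export
fit_surface <- function(points, lambda = 0, side = c("upper", "lower")) {
  side <- match.arg(side)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("`points` must be an N x 3 matrix (x, y, z)")
  if (!all(is.finite(points))) stop("control points must be finite")
  if (!is.finite(lambda) || lambda < 0) stop("`lambda` must be >= 0")
  points <- merge_duplicate_xy(points, tol = 1e-6)
  n <- nrow(points)
  if (n < 3L) stop("need at least 3 control points with distinct (x, y)")
  centroid <- colMeans(points[, 1:2, drop = FALSE])
  xy <- sweep(points[, 1:2, drop = FALSE], 2, centroid)
  z <- points[, 3]
  P <- cbind(1, xy)
  qrP <- qr(P)
  if (qrP$rank < 3L)
    stop("degenerate geometry: control-point footprint is collinear in (x, y)")
  D <- as.matrix(dist(xy))
  K <- matrix(tps_kernel(as.numeric(D)), n, n)
  Kt <- K + diag(lambda, n)
  if (n == 3L) {
    w <- numeric(3)  # three points define the affine part alone
  } else {
    Q <- qr.Q(qrP, complete = TRUE)
    Q2 <- Q[, 4:n, drop = FALSE]
    A <- crossprod(Q2, Kt %*% Q2)
    rc <- rcond(A)
    if (!is.finite(rc) || rc < 1e-15)
      stop(sprintf("singular thin-plate system after regularization (rcond = %.2e)", rc))
    gamma <- solve(A, crossprod(Q2, z))
    w <- as.numeric(Q2 %*% gamma)
  }
  a <- qr.coef(qrP, z - Kt %*% w)
  structure(list(control_xy = points[, 1:2, drop = FALSE],
                 control_z = z,
                 weights = w,
                 affine = as.numeric(a),
                 centroid = as.numeric(centroid),
                 lambda = lambda,
                 side = side),
            class = "tps_surface")
}

merge_duplicate_xy <- function(points, tol = 1e-6) {
  key <- paste(round(points[, 1] / tol), round(points[, 2] / tol))
  if (!anyDuplicated(key)) return(points)
  grp <- match(key, unique(key))
  x <- tapply(points[, 1], grp, mean)
  y <- tapply(points[, 2], grp, mean)
  z <- tapply(points[, 3], grp, mean)
  cbind(as.numeric(x), as.numeric(y), as.numeric(z))
}

#' @export
print.tps_surface <- function(x, ...) {
  cat(sprintf("<tps_surface> %d control points, lambda = %.4g, side = %s\n",
              nrow(x$control_xy), x$lambda, x$side))
  res <- residuals(x)
  cat(sprintf("  control-point residual RMS: %.4g A\n", sqrt(mean(res^2))))
  cat(sprintf("  footprint (A): x [%.4g, %.4g], y [%.4g, %.4g]\n",
              min(x$control_xy[, 1]), max(x$control_xy[, 1]),
              min(x$control_xy[, 2]), max(x$control_xy[, 2])))
  invisible(x)
}

#' Evaluate interface height
#'
#' @param object a [tps_surface][fit_surface].
#' @param xy M x 2 matrix (or length-2 vector) of planar positions
#'   (Angstrom). Positions more than 20% of the footprint diameter outside
#'   the control-point convex hull trigger an extrapolation warning.
#' @param ... unused.
#' @return numeric vector of heights z (Angstrom).
#' @export
predict.tps_surface <- function(object, xy, ...) {
  xy <- rbind_xy(xy)
  warn_extrapolation(object, xy)
  xc <- sweep(xy, 2, object$centroid)
  ctr <- sweep(object$control_xy, 2, object$centroid)
  a <- object$affine
  out <- a[1] + xc %*% a[2:3]
  dx <- outer(xc[, 1], ctr[, 1], `-`)
  dy <- outer(xc[, 2], ctr[, 2], `-`)
  U <- matrix(tps_kernel(sqrt(as.numeric(dx^2 + dy^2))), nrow(xy))
  as.numeric(out + U %*% object$weights)
}

#' Evaluate interface height (alias for `predict`)
#' @inheritParams predict.tps_surface
#' @param surface a [tps_surface][fit_surface].
#' @return numeric vector of heights (Angstrom).
#' @export
evaluate_height <- function(surface, xy) predict(surface, xy)

rbind_xy <- function(xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, nrow = 1)
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2)
  xy
}

warn_extrapolation <- function(surface, xy) {
  ctr <- surface$control_xy
  hull <- ctr[chull(ctr), , drop = FALSE]
  diam <- max(dist(hull))
  d <- dist_outside_hull(xy, hull)
  if (any(d > 0.2 * diam))
    warning(sprintf("%d point(s) lie > 20%% of the footprint diameter outside the control hull; heights are extrapolated",
                    sum(d > 0.2 * diam)))
  invisible(NULL)
}

# Distance from each query point to a convex polygon (0 if inside).
dist_outside_hull <- function(xy, hull) {
  m <- nrow(hull)
  nq <- nrow(xy)
  hx <- hull[, 1]; hy <- hull[, 2]
  nxt <- c(2:m, 1)
  inside <- rep(TRUE, nq)
  dmin <- rep(Inf, nq)
  for (i in seq_len(m)) {
    ax <- hx[i]; ay <- hy[i]; bx <- hx[nxt[i]]; by <- hy[nxt[i]]
    ex <- bx - ax; ey <- by - ay
    # chull returns vertices counter-clockwise? sign handled by testing both
    crossv <- ex * (xy[, 2] - ay) - ey * (xy[, 1] - ax)
    inside <- inside & (crossv <= 1e-9 * max(1, abs(crossv)))
    len2 <- ex^2 + ey^2
    t <- clamp(((xy[, 1] - ax) * ex + (xy[, 2] - ay) * ey) / len2, 0, 1)
    px <- ax + t * ex; py <- ay + t * ey
    dmin <- pmin(dmin, sqrt((xy[, 1] - px)^2 + (xy[, 2] - py)^2))
  }
  # chull output orientation is clockwise in R; recompute inside both ways
  inside2 <- rep(TRUE, nq)
  for (i in seq_len(m)) {
    ax <- hx[i]; ay <- hy[i]; bx <- hx[nxt[i]]; by <- hy[nxt[i]]
    crossv <- (bx - ax) * (xy[, 2] - ay) - (by - ay) * (xy[, 1] - ax)
    inside2 <- inside2 & (crossv >= -1e-9 * max(1, abs(crossv)))
  }
  ifelse(inside | inside2, 0, dmin)
}

#' Control-point residuals of a fitted interface
#'
#' @param object a [tps_surface][fit_surface].
#' @param ... unused.
#' @return numeric vector, observed minus fitted z at the control points.
#' @export
residuals.tps_surface <- function(object, ...) {
  object$control_z - suppressWarnings(predict(object, object$control_xy))
}

# Analytic planar gradient (df/dx, df/dy): dU/dx = (x - xi) (2 log r + 1).
tps_gradient <- function(surface, xy) {
  xy <- rbind_xy(xy)
  xc <- sweep(xy, 2, surface$centroid)
  ctr <- sweep(surface$control_xy, 2, surface$centroid)
  dx <- outer(xc[, 1], ctr[, 1], `-`)
  dy <- outer(xc[, 2], ctr[, 2], `-`)
  r <- sqrt(dx^2 + dy^2)
  g <- 2 * log(r) + 1
  g[r == 0] <- 0
  gx <- (dx * g) %*% surface$weights
  gy <- (dy * g) %*% surface$weights
  cbind(surface$affine[2] + as.numeric(gx),
        surface$affine[3] + as.numeric(gy))
}

#' Unit normal of the interface, pointing toward the air side
#'
#' The raw upward normal of the height field is
#' `(-df/dx, -df/dy, 1) / norm`; for `side = "lower"` it is negated so that
#' the returned normal always points out of the solution slab into the air.
#'
#' @param surface a [tps_surface][fit_surface].
#' @param xy M x 2 matrix or length-2 vector (Angstrom).
#' @return M x 3 matrix of unit vectors.
#' @export
surface_normal <- function(surface, xy) {
  xy <- rbind_xy(xy)
  g <- tps_gradient(surface, xy)
  n <- cbind(-g[, 1], -g[, 2], 1)
  n <- n / sqrt(rowSums(n^2))
  if (surface$side == "lower") n <- -n
  n
}

#' @export
plot.tps_surface <- function(x, ngrid = 40, ...) {
  rx <- range(x$control_xy[, 1]); ry <- range(x$control_xy[, 2])
  gx <- seq(rx[1], rx[2], length.out = ngrid)
  gy <- seq(ry[1], ry[2], length.out = ngrid)
  zz <- suppressWarnings(
    matrix(predict(x, as.matrix(expand.grid(gx, gy))), ngrid))
  graphics::contour(gx, gy, zz, xlab = "x (A)", ylab = "y (A)", ...)
  graphics::points(x$control_xy, pch = 16, cex = 0.5)
  invisible(x)
}

#' Serialize / deserialize a fitted interface
#'
#' The file holds a one-line JSON header (prefixed `#`) with `lambda`,
#' `side`, `centroid` and `affine`, followed by a TSV of control points and
#' spline weights, so a fit can be reloaded exactly.
#'
#' @param surface a [tps_surface][fit_surface].
#' @param path output path.
#' @return `path` invisibly (`write_surface`); a `tps_surface`
#'   (`read_surface`).
#' @export
write_surface <- function(surface, path) {
  hdr <- jsonlite::toJSON(list(lambda = surface$lambda, side = surface$side,
                               centroid = surface$centroid,
                               affine = surface$affine),
                          auto_unbox = TRUE, digits = NA)
  lines <- c(paste0("#", hdr),
             "x\ty\tz\tweight",
             paste(fmt_num(surface$control_xy[, 1], 17),
                   fmt_num(surface$control_xy[, 2], 17),
                   fmt_num(surface$control_z, 17),
                   fmt_num(surface$weights, 17), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(sub("^#", "", lines[1]))
  tab <- read.table(text = lines[-1], header = TRUE, sep = "\t")
  structure(list(control_xy = as.matrix(tab[, c("x", "y")]),
                 control_z = tab$z,
                 weights = tab$weight,
                 affine = as.numeric(hdr$affine),
                 centroid = as.numeric(hdr$centroid),
                 lambda = hdr$lambda,
                 side = hdr$side),
            class = "tps_surface")
}
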