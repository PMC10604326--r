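#' Least-squares sphere fit
#'
#' Fits a sphere to a point cloud by the algebraic (Kasa) linear
#' least-squares formulation, followed by one Gauss-Newton refinement pass
#' on the geometric residuals. This is the estimator used for the humeral
#' head: the articular surface is close to spherical, and the fit is
#' well-conditioned even for partial (cap) coverage.
#'
#' @param points n x 3 matrix of points (mm), n >= 4, not coplanar.
#' @return object of class `sphere_fit` with fields `center`, `radius` and
#'   `rms_residual` (root-mean-square geometric residual, mm).
#' @export
fit_sphere <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 4L) stop("sphere fit needs at least 4 points")
  a <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  qr_a <- qr(a)
  if (qr_a$rank < 4L) stop("degenerate point configuration for sphere fit")
  sol <- qr.coef(qr_a, b)
  center <- sol[1:3]
  r2 <- sol[4] + sum(center^2)
  if (r2 <= 0) stop("degenerate point configuration for sphere fit")
  radius <- sqrt(r2)

  # one Gauss-Newton step on r_i = |p_i - c| - R
  diff <- sweep(points, 2, center)
  dist <- sqrt(rowSums(diff^2))
  if (any(dist < 1e-12)) dist[dist < 1e-12] <- 1e-12
  jac <- cbind(-diff / dist, -1)
  res <- dist - radius
  step <- tryCatch(qr.coef(qr(jac), -res), error = function(e) rep(0, 4))
  step[is.na(step)] <- 0
  center <- center + step[1:3]
  radius <- radius + step[4]
  if (radius <= 0) stop("degenerate point configuration for sphere fit")

  diff <- sweep(points, 2, center)
  res <- sqrt(rowSums(diff^2)) - radius
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 rms_residual = sqrt(mean(res^2))),
            class = "sphere_fit")
}

#' @method print sphere_fit
#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("sphere fit: center (%.3f, %.3f, %.3f) mm, radius %.3f mm, rms %.2g mm\n",
              x$center[1], x$center[2], x$center[3], x$radius, x$rms_residual))
  invisible(x)
}

# Circle fit (Kasa) of 2-D points; returns list(center, radius, rss).
fit_circle_2d <- function(xy) {
  a <- cbind(2 * xy, 1)
  sol <- qr.coef(qr(a), rowSums(xy^2))
  center <- sol[1:2]
  r2 <- sol[3] + sum(center^2)
  radius <- sqrt(max(r2, 0))
  r <- sqrt(rowSums(sweep(xy, 2, center)^2)) - radius
  list(center = center, radius = radius, rss = sum(r^2))
}

#' Least-squares cylinder-axis fit
#'
#' Estimates the axis of a roughly cylindrical point cloud (the humeral
#' diaphysis) as the line minimizing the spread of radial distances.
#' Candidate directions from the covariance eigenvectors initialize a
#' Nelder-Mead refinement over the axis direction; for each direction the
#' optimal axis position is the algebraic circle fit of the points projected
#' onto the orthogonal plane.
#'
#' @param points n x 3 matrix of points (mm), n >= 6, with cylindrical
#'   spread; spherical or otherwise degenerate clouds raise an error.
#' @return object of class `axis_fit` with fields `point` (a point on the
#'   axis), `direction` (unit vector), `radius` (mean radial distance, mm)
#'   and `rms_residual` (rms radial spread about the fitted radius, mm).
#' @export
fit_cylinder_axis <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 6L) stop("cylinder-axis fit needs at least 6 points")
  centroid <- colMeans(points)
  pc <- sweep(points, 2, centroid)
  ev <- eigen(crossprod(pc) / nrow(pc), symmetric = TRUE)

  plane_basis <- function(u) {
    a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v1 <- a - sum(a * u) * u
    v1 <- v1 / sqrt(sum(v1^2))
    v2 <- c(u[2] * v1[3] - u[3] * v1[2],
            u[3] * v1[1] - u[1] * v1[3],
            u[1] * v1[2] - u[2] * v1[1])
    cbind(v1, v2)
  }
  objective_u <- function(u) {
    b <- plane_basis(u)
    fit_circle_2d(pc %*% b)$rss
  }
  sph <- function(u) c(acos(max(-1, min(1, u[3]))), atan2(u[2], u[1]))
  unsph <- function(p) c(sin(p[1]) * cos(p[2]), sin(p[1]) * sin(p[2]), cos(p[1]))

  best <- NULL
  for (k in 1:3) {
    u0 <- ev$vectors[, k]
    opt <- stats::optim(sph(u0), function(p) objective_u(unsph(p)),
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 500))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  u <- unsph(best$par)
  b <- plane_basis(u)
  circ <- fit_circle_2d(pc %*% b)
  point <- centroid + as.numeric(b %*% circ$center)
  rms <- sqrt(circ$rss / nrow(points))
  if (circ$radius <= 0 || rms > 0.2 * circ$radius)
    stop("degenerate (non-cylindrical) point cloud for axis fit")
  structure(list(point = as.numeric(point), direction = as.numeric(u),
                 radius = circ$radius, rms_residual = rms),
            class = "axis_fit")
}

#' @method print axis_fit
#' @export
print.axis_fit <- function(x, ...) {
  cat(sprintf("cylinder axis: direction (%.4f, %.4f, %.4f), radius %.2f mm, rms %.3g mm\n",
              x$direction[1], x$direction[2], x$direction[3], x$radius,
              x$rms_residual))
  invisible(x)
}
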