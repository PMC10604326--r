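#' Closest points on a mesh surface
#'
#' For each query point, the nearest point on the triangulated surface
#' (point-to-triangle, not vertex-to-vertex). Ties are broken by the lowest
#' triangle index, which makes downstream algorithms deterministic.
#'
#' @param points n x 3 matrix of query points.
#' @param mesh a [surface_mesh()].
#' @return list with `point` (n x 3 matrix), `distance` (n), `face` (n,
#'   1-based triangle index).
#' @export
closest_points <- function(points, mesh) {
  stopifnot_mesh(mesh)
  .closest_point_mesh(as.matrix(points), mesh$vertices, mesh$faces)
}

# Kabsch/SVD least-squares rigid transform mapping p onto q (corresponded
# rows); scale is fixed at 1, determinant forced to +1.
kabsch <- function(p, q) {
  pb <- colMeans(p); qb <- colMeans(q)
  h <- crossprod(sweep(p, 2, pb), sweep(q, 2, qb))
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(rot, qb - as.numeric(rot %*% pb))
}

# Centroid + principal-axes pre-alignment with the 4 axis-sign
# disambiguations (det +1 only), scored by mean matched distance.
pca_prealign <- function(source, target, sample_idx) {
  sv <- source$vertices
  tv <- target$vertices
  es <- eigen(stats::cov(sv), symmetric = TRUE)$vectors
  et <- eigen(stats::cov(tv), symmetric = TRUE)$vectors
  if (det(es) < 0) es[, 3] <- -es[, 3]
  if (det(et) < 0) et[, 3] <- -et[, 3]
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  best <- NULL
  for (s in signs) {
    rot <- et %*% diag(s) %*% t(es)
    tr <- rigid_transform(rot, colMeans(tv) - as.numeric(rot %*% colMeans(sv)))
    moved <- apply_transform(tr, sv[sample_idx, , drop = FALSE])
    score <- mean(closest_points(moved, target)$distance)
    if (is.null(best) || score < best$score) best <- list(tr = tr, score = score)
  }
  best
}

#' Rigid iterative closest point registration
#'
#' Aligns `source` onto `target` by alternating nearest-point matching
#' (point-to-surface) and the least-squares rigid (Kabsch) transform. No
#' scaling is performed, so size differences between bones are preserved,
#' and reflections are never absorbed: the returned rotation always has
#' determinant +1. Initial manual alignment is replaced by an automatic
#' centroid + principal-axes pre-alignment.
#'
#' @param source,target [surface_mesh()] objects, roughly overlapping in
#'   size.
#' @param max_iter maximum number of ICP iterations.
#' @param tol convergence tolerance (mm): stop when the rms matched
#'   distance improves by less than `tol`.
#' @param sample maximum number of source vertices used for matching
#'   (deterministic equally spaced subsample).
#' @return a [rigid_transform()] with attributes `rms` (final rms matched
#'   distance, mm) and `iterations`.
#' @export
icp_rigid <- function(source, target, max_iter = 50L, tol = 1e-4,
                      sample = 2000L) {
  stopifnot_mesh(source); stopifnot_mesh(target)
  nv <- nrow(source$vertices)
  sample_idx <- unique(round(seq(1L, nv, length.out = min(sample, nv))))
  pre <- pca_prealign(source, target, sample_idx)
  bbox <- apply(target$vertices, 2, range)
  diag_len <- sqrt(sum((bbox[2, ] - bbox[1, ])^2))
  if (pre$score > diag_len)
    stop("icp_rigid failed to converge: meshes do not overlap after pre-alignment")

  transform <- pre$tr
  pts <- source$vertices[sample_idx, , drop = FALSE]
  prev_rms <- Inf
  iters <- 0L
  rms <- pre$score
  for (it in seq_len(max_iter)) {
    moved <- apply_transform(transform, pts)
    m <- closest_points(moved, target)
    rms <- sqrt(mean(m$distance^2))
    step <- kabsch(moved, m$point)
    transform <- compose_transform(step, transform)
    iters <- it
    if (prev_rms - rms < tol) break
    prev_rms <- rms
  }
  attr(transform, "rms") <- rms
  attr(transform, "iterations") <- iters
  transform
}

#' Generalized Procrustes alignment without scaling
#'
#' Removes rotation and translation differences from a corresponded shape
#' set by iteratively aligning every shape to the current mean with the
#' corresponded-points Kabsch solution (no scaling, so size variation is
#' retained), recomputing the mean until it stabilizes. The mean's centroid
#' is placed at the origin.
#'
#' @param shapes a [shape_set()].
#' @param max_iter maximum number of Procrustes iterations.
#' @param tol convergence threshold on the mean's movement (mm).
#' @return the aligned [shape_set()], with attribute `iterations`.
#' @export
align_set <- function(shapes, max_iter = 100L, tol = 1e-6) {
  stopifnot(inherits(shapes, "shape_set"))
  arr <- shapes$vertices
  m <- dim(arr)[3]
  mean_shape <- apply(arr, c(1, 2), mean)
  iters <- 0L
  for (it in seq_len(max_iter)) {
    for (k in seq_len(m)) {
      tr <- kabsch(arr[, , k], mean_shape)
      arr[, , k] <- apply_transform(tr, arr[, , k])
    }
    new_mean <- apply(arr, c(1, 2), mean)
    movement <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    iters <- it
    if (movement < tol) break
  }
  centroid <- colMeans(mean_shape)
  arr <- sweep(arr, 2, centroid)
  mean_shape <- sweep(mean_shape, 2, centroid)
  # canonical frame from the mean's own geometry (principal axes, signs
  # fixed by third moments) so the result does not depend on input poses
  rot <- canonical_rotation(mean_shape)
  for (k in seq_len(m)) arr[, , k] <- arr[, , k] %*% t(rot)
  out <- shape_set(lapply(seq_len(m), function(k) arr[, , k]),
                   faces = shapes$faces, ids = shapes$ids)
  attr(out, "iterations") <- iters
  out
}

# Rotation taking centred points into their principal-axes frame, with axis
# signs fixed by the sign of the third moment (and det +1).
canonical_rotation <- function(v) {
  ev <- eigen(stats::cov(v), symmetric = TRUE)$vectors
  proj <- v %*% ev
  s <- sign(colSums(proj^3))
  s[s == 0] <- 1
  ev <- sweep(ev, 2, s, "*")
  if (det(ev) < 0) ev[, 3] <- -ev[, 3]
  t(ev)
}

# Sparse graph Laplacian (degree - adjacency) of the template edges.
mesh_laplacian <- function(mesh) {
  e <- mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  adj <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                              x = 1, dims = c(n, n))
  Matrix::Diagonal(n, Matrix::rowSums(adj)) - adj
}

#' Non-rigid template-to-target warping
#'
#' Deforms a template mesh onto a target surface while preserving the
#' template topology, establishing dense correspondence. The deformation is
#' a per-vertex displacement field estimated by non-rigid iterative closest
#' point: at each step every template vertex is matched to its nearest
#' point on the target surface and the displacement field minimizing
#' `sum |x_i + d_i - c_i|^2 + lambda * sum_edges |d_i - d_j|^2`
#' is obtained as a sparse linear least-squares solve (graph-Laplacian
#' stiffness on template edges). The stiffness decreases over the schedule,
#' coarse to fine.
#'
#' The deformation is initialized coarse-to-fine: rigid ICP, then a global
#' affine ICP stage that captures overall stretch (bones differ most in
#' length and girth, and absorbing that globally prevents tangential
#' correspondence drift), then the Laplacian-regularized per-vertex field.
#'
#' @param template a [surface_mesh()], already roughly aligned to the
#'   target (run [icp_rigid()] first; `rigid_prealign = TRUE` does this for
#'   you).
#' @param target a [surface_mesh()].
#' @param stiffness decreasing positive stiffness schedule.
#' @param inner_iter matching/solve iterations per stiffness level.
#' @param rigid_prealign run [icp_rigid()] before warping.
#' @param affine_iter iterations of the global affine initialization stage.
#' @return the warped [surface_mesh()] (template topology) with attributes
#'   `fit_p99` and `fit_mean`: the 99th-percentile and mean vertex-to-target
#'   distances (mm).
#' @export
warp_template <- function(template, target,
                          stiffness = c(1000, 100, 10, 1),
                          inner_iter = 10L, rigid_prealign = TRUE,
                          affine_iter = 10L) {
  stopifnot_mesh(template); stopifnot_mesh(target)
  if (any(diff(stiffness) >= 0) || any(stiffness <= 0))
    stop("stiffness must be a decreasing positive schedule")
  x <- template$vertices
  if (rigid_prealign) {
    tr <- icp_rigid(template, target)
    x <- apply_transform(tr, x)
  }
  for (it in seq_len(affine_iter)) {
    m <- closest_points(x, target)
    beta <- qr.coef(qr(cbind(x, 1)), m$point)
    x <- cbind(x, 1) %*% beta
  }
  lap <- mesh_laplacian(template)
  n <- nrow(x)
  eye <- Matrix::Diagonal(n)
  for (lambda in stiffness) {
    sys <- Matrix::Cholesky(eye + lambda * lap, LDL = FALSE)
    for (it in seq_len(inner_iter)) {
      m <- closest_points(x, target)
      d <- Matrix::solve(sys, m$point - x)
      x <- x + as.matrix(d)
    }
  }
  m <- closest_points(x, target)
  fit_p99 <- as.numeric(stats::quantile(m$distance, 0.99))
  if (mean(m$distance) > 10 * mean_edge_length(target))
    stop(sprintf(paste0("warp failed to approach the target surface ",
                        "(mean distance %.2f mm, p99 %.2f mm)"),
                 mean(m$distance), fit_p99))
  out <- surface_mesh(x, template$faces)
  attr(out, "fit_p99") <- fit_p99
  attr(out, "fit_mean") <- mean(m$distance)
  out
}
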