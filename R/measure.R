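#' Humeral coordinate system
#'
#' Bone-fixed right-handed frame following the ISB-style construction: the
#' origin is the center of a sphere fitted to the articular surface; the
#' y-axis runs from the midpoint of the two distal epicondyles through the
#' origin (pointing proximally); the x-axis is the normal of the plane
#' through the origin and the two caudal epicondyle points, oriented
#' laterally (from the medial towards the lateral epicondyle); the z-axis
#' completes the right-handed triad (`z = x cross y`, with x recomputed as
#' `y cross z` so the triad is exactly orthonormal).
#'
#' @param mesh a [surface_mesh()].
#' @param landmarks landmark list with `articular_surface`,
#'   `epicondyle_medial_caudal` and `epicondyle_lateral_caudal` vertex
#'   indices (see [build_template()]).
#' @return object of class `humeral_cs` with fields `origin`, `x_axis`,
#'   `y_axis`, `z_axis` and `head_radius` (radius of the fitted head
#'   sphere, mm).
#' @export
build_hcs <- function(mesh, landmarks) {
  stopifnot_mesh(mesh)
  art <- mesh$vertices[landmarks$articular_surface, , drop = FALSE]
  sph <- fit_sphere(art)
  origin <- sph$center
  em <- mesh$vertices[landmarks$epicondyle_medial_caudal[1], ]
  el <- mesh$vertices[landmarks$epicondyle_lateral_caudal[1], ]
  ep_mid <- (em + el) / 2

  y <- origin - ep_mid
  ylen <- sqrt(sum(y^2))
  if (ylen < 1e-9) stop("degenerate landmark configuration (epicondyle midpoint at head center)")
  y <- y / ylen

  n <- cross3(em - origin, el - origin)
  nlen <- sqrt(sum(n^2))
  if (nlen < 1e-9) stop("collinear landmark configuration for the x-axis plane")
  x <- n / nlen
  if (sum(x * (el - em)) < 0) x <- -x      # orient laterally

  z <- cross3(x, y)
  z <- z / sqrt(sum(z^2))
  x <- cross3(y, z)
  structure(list(origin = origin, x_axis = x, y_axis = y, z_axis = z,
                 head_radius = sph$radius),
            class = "humeral_cs")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @method print humeral_cs
#' @export
print.humeral_cs <- function(x, ...) {
  cat(sprintf("humeral coordinate system: origin (%.1f, %.1f, %.1f) mm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  y-axis (proximal): (%.3f, %.3f, %.3f)\n",
              x$y_axis[1], x$y_axis[2], x$y_axis[3]))
  invisible(x)
}

#' Maximum humerus length
#'
#' Distance between the two extreme supporting planes normal to the HCS
#' y-axis (the most proximal and most distal vertex planes), i.e. the
#' maximum extent of the bone along its anatomical long axis.
#'
#' @param mesh a [surface_mesh()].
#' @param hcs a [build_hcs()] frame.
#' @return length in mm.
#' @export
measure_max_length <- function(mesh, hcs) {
  stopifnot_mesh(mesh)
  proj <- as.numeric(mesh$vertices %*% hcs$y_axis)
  max(proj) - min(proj)
}

#' Humeral head radius
#'
#' Radius of the least-squares sphere fitted to the articular-surface
#' vertices.
#'
#' @param mesh a [surface_mesh()].
#' @param landmarks landmark list with an `articular_surface` index set.
#' @return radius in mm.
#' @export
measure_head_radius <- function(mesh, landmarks) {
  stopifnot_mesh(mesh)
  if (!length(landmarks$articular_surface))
    stop("articular landmark set is empty")
  fit_sphere(mesh$vertices[landmarks$articular_surface, , drop = FALSE])$radius
}

# Intersection contours of a mesh with a plane: list of closed polygons
# (matrices of 3-D points). Segments are keyed by the mesh edges they
# cross, so chaining is exact and deterministic.
mesh_plane_contours <- function(mesh, plane) {
  d <- as.numeric(signed_plane_distance(mesh$vertices, plane))
  # vertices exactly on the plane would break the segment chaining; nudge
  # them to one side (perimeter error is O(1e-9) mm)
  d[abs(d) < 1e-9] <- 1e-9
  f <- mesh$faces
  s <- matrix(d[f], ncol = 3)
  straddle <- which(rowSums(s > 0) > 0 & rowSums(s < 0) > 0)
  if (!length(straddle)) return(list())

  edge_key <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
  seg_edges <- vector("list", length(straddle))
  pts <- new.env(hash = TRUE, parent = emptyenv())
  for (si in seq_along(straddle)) {
    tri <- f[straddle[si], ]
    dd <- d[tri]
    keys <- character(0)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      i <- tri[e[1]]; j <- tri[e[2]]
      if ((dd[e[1]] > 0) != (dd[e[2]] > 0)) {
        key <- edge_key(i, j)
        if (is.null(pts[[key]])) {
          t <- d[i] / (d[i] - d[j])
          assign(key, mesh$vertices[i, ] + t * (mesh$vertices[j, ] - mesh$vertices[i, ]),
                 envir = pts)
        }
        keys <- c(keys, key)
      }
    }
    seg_edges[[si]] <- keys
  }
  seg_edges <- seg_edges[vapply(seg_edges, length, 1L) == 2L]
  if (!length(seg_edges)) return(list())

  # chain segments into loops via shared edge keys
  conn <- new.env(hash = TRUE, parent = emptyenv())
  for (si in seq_along(seg_edges)) {
    for (key in seg_edges[[si]]) {
      conn[[key]] <- c(conn[[key]], si)
    }
  }
  used <- logical(length(seg_edges))
  contours <- list()
  for (start in seq_along(seg_edges)) {
    if (used[start]) next
    loop_keys <- character(0)
    cur <- start
    key <- seg_edges[[cur]][1]
    repeat {
      used[cur] <- TRUE
      loop_keys <- c(loop_keys, key)
      nxt_key <- setdiff(seg_edges[[cur]], key)[1]
      if (is.na(nxt_key)) break
      cand <- setdiff(conn[[nxt_key]], cur)
      cand <- cand[!used[cand]]
      key <- nxt_key
      if (!length(cand)) break
      cur <- cand[1]
    }
    pts_mat <- do.call(rbind, lapply(loop_keys, function(k) pts[[k]]))
    if (nrow(pts_mat) >= 3L) contours[[length(contours) + 1L]] <- pts_mat
  }
  contours
}

polygon_perimeter <- function(pts) {
  nxt <- c(seq_len(nrow(pts))[-1], 1L)
  sum(sqrt(rowSums((pts[nxt, , drop = FALSE] - pts)^2)))
}

point_in_polygon_2d <- function(pt, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((poly[i, 2] > pt[2]) != (poly[j, 2] > pt[2]) &&
        pt[1] < (poly[j, 1] - poly[i, 1]) * (pt[2] - poly[i, 2]) /
          (poly[j, 2] - poly[i, 2]) + poly[i, 1])
      inside <- !inside
    j <- i
  }
  inside
}

#' Shaft circumference at the deltoid tuberosity level
#'
#' Cuts the bone with the plane normal to the HCS y-axis through the
#' deltoid-tuberosity landmark (the most protruding mid-diaphysis point)
#' and measures the perimeter of the closed cross-section contour that
#' encloses the shaft axis.
#'
#' @param mesh a [surface_mesh()].
#' @param hcs a [build_hcs()] frame.
#' @param landmarks landmark list with a `deltoid_tuberosity` vertex index.
#' @return perimeter in mm.
#' @export
measure_shaft_circumference <- function(mesh, hcs, landmarks) {
  stopifnot_mesh(mesh)
  if (!length(landmarks$deltoid_tuberosity))
    stop("deltoid tuberosity landmark is missing")
  p_delt <- mesh$vertices[landmarks$deltoid_tuberosity[1], ]
  pl <- plane3(p_delt, hcs$y_axis)
  contours <- mesh_plane_contours(mesh, pl)
  if (!length(contours)) stop("section plane does not intersect the mesh")
  # shaft-axis point at this level: on the y-axis line through the origin
  axis_pt <- hcs$origin +
    sum((p_delt - hcs$origin) * hcs$y_axis) * hcs$y_axis
  b <- cbind(hcs$x_axis, hcs$z_axis)
  pt2 <- as.numeric((axis_pt - pl$point) %*% b)
  for (ct in contours) {
    poly2 <- sweep(ct, 2, pl$point) %*% b
    if (point_in_polygon_2d(pt2, poly2)) return(polygon_perimeter(ct))
  }
  stop("no cross-section contour encloses the shaft axis")
}

#' Take a set of anatomical measurements
#'
#' @param mesh a [surface_mesh()].
#' @param hcs optional [build_hcs()] frame (built from the landmarks when
#'   `NULL`).
#' @param landmarks landmark list (see [build_template()]).
#' @param which non-empty subset of `c("max_length", "head_radius",
#'   "shaft_circumference")`.
#' @return named list of class `measurement_set` with the requested values
#'   (mm).
#' @export
measure_all <- function(mesh, hcs = NULL, landmarks,
                        which = c("max_length", "head_radius",
                                  "shaft_circumference")) {
  if (!length(which)) stop("at least one measurement must be requested")
  which <- match.arg(which, several.ok = TRUE)
  if (is.null(hcs)) hcs <- build_hcs(mesh, landmarks)
  out <- list()
  if ("max_length" %in% which)
    out$max_length <- measure_max_length(mesh, hcs)
  if ("head_radius" %in% which)
    out$head_radius <- measure_head_radius(mesh, landmarks)
  if ("shaft_circumference" %in% which)
    out$shaft_circumference <- measure_shaft_circumference(mesh, hcs, landmarks)
  if (!is.null(out$max_length) && !is.null(out$head_radius) &&
      out$head_radius >= out$max_length)
    stop("implausible measurements: head radius exceeds bone length")
  structure(out, class = "measurement_set")
}

#' @method print measurement_set
#' @export
print.measurement_set <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("  %s: %.2f mm\n", nm, x[[nm]]))
  invisible(x)
}

#' Intraclass correlation coefficient for repeated measurements
#'
#' Two-way mixed-effects, absolute-agreement, single-measure ICC (the
#' common reliability index for one observer repeating a measurement),
#' computed from the two-way ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))` with `k = 2`
#' sessions and `n` subjects.
#'
#' @param rep1,rep2 numeric vectors of paired measurements (length >= 3).
#' @return ICC value in `[-1, 1]`; 0 (with a warning) when there is no
#'   between-subject variance.
#' @export
icc <- function(rep1, rep2) {
  stopifnot(length(rep1) == length(rep2))
  n <- length(rep1)
  if (n < 3L) stop("ICC needs at least 3 subjects")
  x <- cbind(rep1, rep2)
  k <- 2
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((x - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr < 1e-300) {
    warning("no between-subject variance; ICC undefined, returning 0")
    return(0)
  }
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}
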