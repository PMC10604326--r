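#' Triangle surface mesh
#'
#' Constructs a triangle surface mesh, the universal shape carrier of the
#' package. Coordinates are interpreted as millimetres throughout (the CT
#' export convention; STL files carry no unit information).
#'
#' Zero-area (degenerate) faces are dropped at construction time, so a valid
#' `surface_mesh` never contains them. Face indices are 1-based.
#'
#' @param vertices numeric matrix with one row per vertex and 3 columns (mm).
#' @param faces integer matrix with one row per triangle and 3 columns of
#'   vertex indices.
#' @return An object of class `surface_mesh`: a list with elements
#'   `vertices` and `faces`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(vertices) <= 3L) stop("mesh must have more than 3 vertices")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  if (nrow(faces) < 1L) stop("mesh must have at least one face")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  areas <- triangle_areas(vertices, faces)
  keep <- areas > 1e-12
  if (!any(keep)) stop("all faces are degenerate")
  faces <- faces[keep, , drop = FALSE]
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @method print surface_mesh
#' @export
print.surface_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("surface_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bounding box [mm]: x %.1f..%.1f  y %.1f..%.1f  z %.1f..%.1f\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  cat(sprintf("  surface area %.1f mm^2, mean edge length %.2f mm\n",
              mesh_area(x), mean_edge_length(x)))
  invisible(x)
}

is_surface_mesh <- function(x) inherits(x, "surface_mesh")

stopifnot_mesh <- function(mesh) {
  if (!is_surface_mesh(mesh)) stop("expected a surface_mesh object")
}

triangle_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c <- vertices[faces[, 3], , drop = FALSE]
  u <- b - a
  v <- c - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  u <- v[f[, 2], , drop = FALSE] - a
  w <- v[f[, 3], , drop = FALSE] - a
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Total surface area of a mesh
#'
#' @param mesh a [surface_mesh()].
#' @return total triangle area in mm^2.
#' @export
mesh_area <- function(mesh) {
  stopifnot_mesh(mesh)
  sum(triangle_areas(mesh$vertices, mesh$faces))
}

#' Per-vertex area weights (one third of incident triangle areas)
#' @noRd
vertex_areas <- function(mesh) {
  areas <- triangle_areas(mesh$vertices, mesh$faces)
  w <- numeric(nrow(mesh$vertices))
  for (k in 1:3) {
    acc <- tapply(areas, mesh$faces[, k], sum)
    idx <- as.integer(names(acc))
    w[idx] <- w[idx] + acc
  }
  w / 3
}

#' Unique undirected edges of a mesh
#' @noRd
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(e), , drop = FALSE]
}

#' Mean triangular edge length
#'
#' Arithmetic mean of the lengths of the unique (undirected) edges of the
#' mesh. Clinical humerus meshes in this pipeline are remeshed to a mean
#' edge length around 1.5 mm; this is the check used for that convention.
#'
#' @param mesh a [surface_mesh()].
#' @return mean edge length in mm.
#' @export
mean_edge_length <- function(mesh) {
  stopifnot_mesh(mesh)
  e <- mesh_edges(mesh)
  d <- mesh$vertices[e[, 1], , drop = FALSE] - mesh$vertices[e[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' An oriented plane in 3-space
#'
#' @param point a point on the plane (mm).
#' @param normal plane normal; normalized internally, must be non-zero.
#' @return object of class `plane3` with unit `normal`.
#' @export
plane3 <- function(point, normal) {
  point <- as.numeric(point)
  normal <- as.numeric(normal)
  stopifnot(length(point) == 3L, length(normal) == 3L,
            all(is.finite(point)), all(is.finite(normal)))
  len <- sqrt(sum(normal^2))
  if (len < 1e-12) stop("plane normal must be non-zero")
  structure(list(point = point, normal = normal / len), class = "plane3")
}

signed_plane_distance <- function(points, plane) {
  sweep(points, 2, plane$point) %*% plane$normal
}

#' Mirror a mesh across a plane
#'
#' Reflects all vertices across the plane and flips the face orientation so
#' that outward normals remain outward (a reflection alone would turn the
#' mesh inside out). Used to mirror right humeri to the left before model
#' building and for the contralateral-registration baseline.
#'
#' @param mesh a [surface_mesh()].
#' @param plane a [plane3()]; default is the sagittal plane x = 0.
#' @return the mirrored `surface_mesh`.
#' @export
mirror_mesh <- function(mesh, plane = plane3(c(0, 0, 0), c(1, 0, 0))) {
  stopifnot_mesh(mesh)
  d <- as.numeric(signed_plane_distance(mesh$vertices, plane))
  v <- mesh$vertices - 2 * outer(d, plane$normal)
  surface_mesh(v, mesh$faces[, c(1, 3, 2), drop = FALSE])
}

#' Cut a mesh by a plane, keeping one open half
#'
#' Triangles straddling the plane are split along the intersection line; the
#' returned mesh lies entirely in the kept closed half-space. The cut
#' boundary is left as an open polyline (no cap), because downstream
#' surface-deviation statistics must not be polluted by an artificial cut
#' face.
#'
#' @param mesh a [surface_mesh()].
#' @param plane a [plane3()].
#' @param keep `"positive"` to keep the half-space the plane normal points
#'   into, `"negative"` for the other side.
#' @return the kept part as a `surface_mesh`.
#' @export
cut_mesh_by_plane <- function(mesh, plane, keep = c("positive", "negative")) {
  stopifnot_mesh(mesh)
  keep <- match.arg(keep)
  tol <- 1e-9
  d <- as.numeric(signed_plane_distance(mesh$vertices, plane))
  if (keep == "negative") d <- -d

  pos <- d > tol
  neg <- d < -tol
  f <- mesh$faces
  fpos <- matrix(pos[f], ncol = 3)
  fneg <- matrix(neg[f], ncol = 3)
  npos <- rowSums(fpos)
  nneg <- rowSums(fneg)

  keep_whole <- nneg == 0L
  drop_whole <- npos == 0L
  straddle <- which(!keep_whole & !drop_whole)

  if (all(drop_whole)) stop("cut removes the entire mesh")
  if (length(straddle) == 0L && !any(drop_whole))
    return(surface_mesh(mesh$vertices, f))

  verts <- mesh$vertices
  new_faces <- f[keep_whole, , drop = FALSE]
  new_faces <- lapply(seq_len(nrow(new_faces)), function(i) new_faces[i, ])

  # cache of intersection vertices keyed by the cut edge, so neighbours share
  edge_cache <- new.env(hash = TRUE, parent = emptyenv())
  isect <- function(i, j) {
    key <- paste0(min(i, j), "_", max(i, j))
    idx <- edge_cache[[key]]
    if (!is.null(idx)) return(idx)
    t <- d[i] / (d[i] - d[j])
    p <- verts[i, ] + t * (verts[j, ] - verts[i, ])
    verts <<- rbind(verts, p)
    idx <- nrow(verts)
    assign(key, idx, envir = edge_cache)
    idx
  }

  for (fi in straddle) {
    tri <- f[fi, ]
    s <- ifelse(pos[tri], 1L, ifelse(neg[tri], -1L, 0L))
    # rotate so the configuration is canonical
    for (r in 0:2) {
      tri_r <- tri[((0:2 + r) %% 3) + 1]
      s_r <- s[((0:2 + r) %% 3) + 1]
      if (sum(s_r > 0) == 1L && s_r[1] > 0) { tri <- tri_r; s <- s_r; break }
      if (sum(s_r > 0) == 2L && s_r[1] < 0) { tri <- tri_r; s <- s_r; break }
    }
    if (sum(s > 0) == 1L) {
      a <- tri[1]; b <- tri[2]; c <- tri[3]
      if (s[2] < 0 && s[3] < 0) {              # + - -
        pab <- isect(a, b); pca <- isect(c, a)
        new_faces[[length(new_faces) + 1L]] <- c(a, pab, pca)
      } else if (s[2] < 0 && s[3] == 0L) {     # + - 0
        pab <- isect(a, b)
        new_faces[[length(new_faces) + 1L]] <- c(a, pab, c)
      } else if (s[2] == 0L && s[3] < 0) {     # + 0 -
        pca <- isect(c, a)
        new_faces[[length(new_faces) + 1L]] <- c(a, b, pca)
      }
    } else {                                    # two positive: - + +
      a <- tri[1]; b <- tri[2]; c <- tri[3]
      pab <- isect(a, b); pca <- isect(c, a)
      new_faces[[length(new_faces) + 1L]] <- c(pab, b, c)
      new_faces[[length(new_faces) + 1L]] <- c(pab, c, pca)
    }
  }

  faces_mat <- do.call(rbind, new_faces)
  # drop unreferenced vertices, remap indices
  used <- sort(unique(as.integer(faces_mat)))
  remap <- integer(nrow(verts))
  remap[used] <- seq_along(used)
  faces_mat <- matrix(remap[faces_mat], ncol = 3)
  surface_mesh(verts[used, , drop = FALSE], faces_mat)
}

#' Rigid transform (rotation + translation, no scaling)
#'
#' @param rotation 3x3 rotation matrix, orthonormal with determinant +1.
#' @param translation length-3 translation vector (mm).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal")
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation must have determinant +1 (reflections are not rigid)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to points or a mesh
#'
#' @param transform a [rigid_transform()].
#' @param x an n x 3 matrix of points or a [surface_mesh()].
#' @return transformed points or mesh, matching the input type.
#' @export
apply_transform <- function(transform, x) {
  if (is_surface_mesh(x)) {
    v <- apply_transform(transform, x$vertices)
    return(surface_mesh(v, x$faces))
  }
  sweep(as.matrix(x) %*% t(transform$rotation), 2, -transform$translation)
}

#' Compose rigid transforms (`second` applied after `first`)
#' @param first,second [rigid_transform()] objects.
#' @return the composed `rigid_transform`.
#' @export
compose_transform <- function(second, first) {
  rigid_transform(second$rotation %*% first$rotation,
                  as.numeric(second$rotation %*% first$translation) +
                    second$translation)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, as.numeric(-rt %*% transform$translation))
}

#' Rotation matrix about an axis
#' @param axis rotation axis (normalized internally).
#' @param angle angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  k <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}
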