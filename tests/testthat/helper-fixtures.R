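# Shared fixtures, built in code and cached for the duration of a test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  hit <- .fixture_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- builder()
  assign(key, val, envir = .fixture_cache)
  val
}

# canonical templates at the resolutions the tests use
test_template <- function(resolution = 4) {
  cached(paste0("tpl_", resolution), function() build_template(resolution))
}

# a coarse segment-correspondence template shared by the comparison tests
test_segment_template <- function(n_points = 800) {
  cached(paste0("segtpl_", n_points), function()
    humerusSSM:::default_segment_template(n_points, 60))
}

# unit tetrahedron: smallest closed mesh
tetra_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  surface_mesh(v, f)
}

# regular icosahedron with the given edge length
icosahedron_mesh <- function(edge = 2) {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, p, 0), c(1, p, 0), c(-1, -p, 0), c(1, -p, 0),
             c(0, -1, p), c(0, 1, p), c(0, -1, -p), c(0, 1, -p),
             c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1))
  v <- v * (edge / 2)                     # raw edge length is 2
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  surface_mesh(v, f)
}

# axis-aligned cube of side L with one corner at the origin
cube_mesh <- function(side = 10) {
  v <- as.matrix(expand.grid(c(0, side), c(0, side), c(0, side)))
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  surface_mesh(v, f)
}

# UV-sphere of radius r centred at `center`
uv_sphere_mesh <- function(r, n = 40, center = c(0, 0, 0)) {
  th <- seq(0, pi, length.out = n)[-c(1, n)]
  ph <- seq(0, 2 * pi, length.out = 2 * n + 1)[-(2 * n + 1)]
  g <- expand.grid(th = th, ph = ph)
  v <- cbind(r * sin(g$th) * cos(g$ph), r * sin(g$th) * sin(g$ph),
             r * cos(g$th))
  v <- rbind(v, c(0, 0, r), c(0, 0, -r))
  nr <- length(th); nc <- length(ph)
  idx <- function(i, j) (j - 1) * nr + i
  fs <- vector("list", 2 * nc * nr)
  k <- 0
  for (j in seq_len(nc)) {
    jn <- j %% nc + 1
    for (i in seq_len(nr - 1)) {
      fs[[k <- k + 1]] <- c(idx(i, j), idx(i, jn), idx(i + 1, j))
      fs[[k <- k + 1]] <- c(idx(i + 1, j), idx(i, jn), idx(i + 1, jn))
    }
    fs[[k <- k + 1]] <- c(nrow(v) - 1, idx(1, jn), idx(1, j))
    fs[[k <- k + 1]] <- c(nrow(v), idx(nr, j), idx(nr, jn))
  }
  m <- surface_mesh(sweep(v, 2, -center), do.call(rbind, fs[seq_len(k)]))
  if (humerusSSM:::mesh_signed_volume(m) < 0)
    m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# open cylinder tube along z (no caps), radius r, height h
cylinder_mesh <- function(r = 10, h = 100, n_theta = 48, n_z = 30) {
  th <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  z <- seq(0, h, length.out = n_z)
  v <- do.call(rbind, lapply(z, function(zz) cbind(r * cos(th), r * sin(th), zz)))
  jn <- c(seq_len(n_theta)[-1], 1L)
  fs <- vector("list", n_z - 1)
  for (i in seq_len(n_z - 1)) {
    a <- (i - 1) * n_theta + seq_len(n_theta)
    b <- i * n_theta + seq_len(n_theta)
    fs[[i]] <- rbind(cbind(a, a[jn], b), cbind(b, a[jn], b[jn]))
  }
  surface_mesh(v, do.call(rbind, fs))
}

# outward vertex normals (area-weighted average of incident face normals)
vertex_normals <- function(mesh) {
  fn <- humerusSSM:::face_normals(mesh)
  vn <- matrix(0, nrow(mesh$vertices), 3)
  for (k in 1:3) {
    for (d in 1:3) {
      acc <- tapply(fn[, d], mesh$faces[, k], sum)
      i <- as.integer(names(acc))
      vn[i, d] <- vn[i, d] + acc
    }
  }
  vn / sqrt(rowSums(vn^2))
}

rotation_angle <- function(r) acos(pmin(1, pmax(-1, (sum(diag(r)) - 1) / 2)))

random_rigid <- function() {
  rigid_transform(rotation_about_axis(stats::rnorm(3), stats::runif(1, 0.1, 1.2)),
                  stats::rnorm(3, sd = 15))
}

# latent-sd conventions of a healthy adult population (generator defaults)
population_sds <- c(length = 20, head_radius = 1.5, shaft_radius = 1,
                    neck_shaft_angle = 4, head_offset = 1,
                    deltoid_prominence = 0.4, epicondyle_width = 3)

sds_zero_except <- function(...) {
  keep <- c(...)
  sds <- stats::setNames(numeric(length(population_sds)), names(population_sds))
  sds[keep] <- population_sds[keep]
  sds
}
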