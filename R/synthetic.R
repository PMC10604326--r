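#' Latent parameters of a synthetic humerus
#'
#' The generator describes a humerus-like bone by seven interpretable
#' factors. Defaults are generator conventions chosen from general adult
#' anatomical ranges so that the measurement operators produce realistic
#' magnitudes.
#'
#' @param length maximum bone length along the long axis (mm).
#' @param head_radius radius of the articular head sphere (mm); must be
#'   below `length / 4`.
#' @param shaft_radius mid-diaphysis radius (mm); must be below
#'   `head_radius`.
#' @param neck_shaft_angle angle between shaft axis and head/neck axis
#'   (degrees), in (110, 160).
#' @param head_offset medial offset of the head center from the shaft axis
#'   (mm).
#' @param deltoid_prominence height of the deltoid-tuberosity bump (mm).
#' @param epicondyle_width mediolateral width across the epicondylar region
#'   (mm).
#' @return a named numeric vector of class `humerus_latent`.
#' @export
humerus_latent <- function(length = 310, head_radius = 24, shaft_radius = 10,
                           neck_shaft_angle = 135, head_offset = 6,
                           deltoid_prominence = 2, epicondyle_width = 60) {
  lat <- c(length = length, head_radius = head_radius,
           shaft_radius = shaft_radius, neck_shaft_angle = neck_shaft_angle,
           head_offset = head_offset, deltoid_prominence = deltoid_prominence,
           epicondyle_width = epicondyle_width)
  validate_latent(lat)
  structure(lat, class = "humerus_latent")
}

latent_fields <- c("length", "head_radius", "shaft_radius",
                   "neck_shaft_angle", "head_offset", "deltoid_prominence",
                   "epicondyle_width")

validate_latent <- function(lat) {
  if (!all(latent_fields %in% names(lat))) stop("missing latent fields")
  if (any(!is.finite(lat))) stop("latent values must be finite")
  if (any(lat[c("length", "head_radius", "shaft_radius",
                "epicondyle_width")] <= 0))
    stop("latent lengths must be positive")
  if (lat["deltoid_prominence"] < 0)
    stop("deltoid_prominence must be non-negative")
  if (lat["head_radius"] >= lat["length"] / 4)
    stop("head_radius must be below length/4")
  if (lat["shaft_radius"] >= lat["head_radius"])
    stop("shaft_radius must be below head_radius")
  if (lat["neck_shaft_angle"] <= 110 || lat["neck_shaft_angle"] >= 160)
    stop("neck_shaft_angle must lie in (110, 160) degrees")
  invisible(lat)
}

latent_ok <- function(lat) {
  isTRUE(tryCatch({validate_latent(lat); TRUE}, error = function(e) FALSE))
}

smoothstep <- function(t) {
  t <- pmin(1, pmax(0, t))
  t * t * (3 - 2 * t)
}

# Region boundaries and head placement derived from a latent vector.
# Everything is (piecewise) affine in the latent where possible, so that a
# population driven by k latent factors is captured by ~k linear modes.
latent_geometry <- function(lat) {
  L <- lat[["length"]]; R <- lat[["head_radius"]]
  alpha <- lat[["neck_shaft_angle"]] * pi / 180
  list(
    L = L, R = R, rs = lat[["shaft_radius"]],
    dp = lat[["deltoid_prominence"]], ew = lat[["epicondyle_width"]],
    x_h = lat[["head_offset"]] - 0.25 * R * cos(alpha),
    z_h = L - R,
    z_cap = L - R - 0.55 * R,      # start of the purely spherical cap
    z_nb = L - R - 1.6 * R,        # start of the neck blend
    z_d1 = 0.18 * L                # top of the distal (epicondylar) region
  )
}

#' Build the canonical humerus template
#'
#' Constructs a humerus-like triangle mesh with a fixed, structured
#' topology: a circular-section shaft along the long (z) axis, a deltoid
#' tuberosity bump on the lateral side at mid-diaphysis, an epicondylar
#' widening and trochlear taper distally, and a spherical articular cap
#' proximally, tilted/offset medially according to the neck-shaft angle and
#' head offset. Landmark vertex sets are identified constructively during
#' generation. Every instantiation of the template shares this topology, so
#' dense correspondence is exact by construction.
#'
#' @param resolution target mean edge length in mm, in `[0.5, 5]`.
#' @param latent default latent used to lay out the ring structure.
#' @return object of class `humerus_template` with elements `mesh`
#'   (a [surface_mesh()]), `landmarks` (named list of vertex-index sets),
#'   `latent`, `resolution`, plus the internal ring layout.
#' @export
build_template <- function(resolution = 1.5, latent = humerus_latent()) {
  if (!is.numeric(resolution) || resolution < 0.5 || resolution > 5)
    stop("resolution must lie in [0.5, 5] mm")
  validate_latent(latent)
  geo <- latent_geometry(latent)

  n_theta <- max(12L, 2L * round(pi * 12 / resolution))  # even by design
  dz <- 0.82 * resolution

  psi_cap <- acos(-0.55)
  # topmost cap ring: stop where the ring circumference gets too small and
  # close with a fan to the pole
  r_top <- max(0.5 * resolution * n_theta / (2 * pi), 0.12 * geo$R)
  psi_top <- asin(min(0.9, r_top / geo$R))
  n_cap <- max(4L, ceiling((psi_cap - psi_top) * geo$R / dz))
  n_blend <- max(3L, ceiling((geo$z_cap - geo$z_nb) / dz))
  n_shaft <- max(4L, 2L * ceiling((geo$z_nb - geo$z_d1) / dz / 2))  # even
  gap_frac <- min(0.03, 0.6 * resolution / geo$L)
  n_dist <- max(4L, ceiling(geo$z_d1 * (1 - gap_frac) / dz))

  # ring table: region label + normalized coordinate within the region
  rings <- rbind(
    data.frame(region = "distal", t = seq(0, 1, length.out = n_dist)),
    data.frame(region = "shaft", t = seq_len(n_shaft) / n_shaft),
    data.frame(region = "blend", t = seq_len(n_blend - 1) / n_blend),
    data.frame(region = "cap",
               t = seq(1, 0, length.out = n_cap))  # psi fraction, 1 = cap base
  )
  layout <- list(n_theta = n_theta, rings = rings, gap_frac = gap_frac,
                 psi_cap = psi_cap, psi_top = psi_top,
                 theta = 2 * pi * (seq_len(n_theta) - 1) / n_theta)

  n_rings <- nrow(rings)
  n_vert <- n_rings * n_theta + 2L
  bottom_pole <- n_vert - 1L
  top_pole <- n_vert

  # faces: bottom fan, ring bands, top fan
  ring_idx <- function(i) (i - 1L) * n_theta + seq_len(n_theta)
  jn <- c(seq_len(n_theta)[-1], 1L)   # next theta index, wrapped
  faces <- vector("list", n_rings + 1L)
  r1 <- ring_idx(1L)
  faces[[1]] <- cbind(bottom_pole, r1[jn], r1)
  for (i in seq_len(n_rings - 1L)) {
    a <- ring_idx(i); b <- ring_idx(i + 1L)
    faces[[i + 1L]] <- rbind(cbind(a, a[jn], b), cbind(b, a[jn], b[jn]))
  }
  rn <- ring_idx(n_rings)
  faces[[n_rings + 1L]] <- cbind(top_pole, rn, rn[jn])
  faces <- do.call(rbind, faces)

  # landmarks
  theta <- layout$theta
  j_med <- which.min(abs(theta))            # +x = medial
  j_lat <- which.min(abs(theta - pi))       # -x = lateral
  dist_rows <- which(rings$region == "distal")
  t_e <- ((0.05 - gap_frac) / (0.18 - gap_frac))  # epicondylar level in t
  i_epi <- dist_rows[which.min(abs(rings$t[dist_rows] - t_e))]
  shaft_rows <- which(rings$region == "shaft")
  i_delt <- shaft_rows[which.min(abs(rings$t[shaft_rows] - 0.5))]
  cap_rows <- which(rings$region == "cap")
  psi_art <- acos(-0.45)
  art_rows <- cap_rows[psi_top + rings$t[cap_rows] * (psi_cap - psi_top) <=
                         psi_art]
  landmarks <- list(
    articular_surface = c(as.integer(sapply(art_rows, ring_idx)), top_pole),
    epicondyle_medial_caudal = ring_idx(i_epi)[j_med],
    epicondyle_lateral_caudal = ring_idx(i_epi)[j_lat],
    trochlea_inferior = bottom_pole,
    head_superior = top_pole,
    deltoid_tuberosity = ring_idx(i_delt)[j_lat]
  )
  layout$i_epi <- i_epi
  layout$i_delt <- i_delt
  layout$t_e <- t_e
  layout$bottom_pole <- bottom_pole
  layout$top_pole <- top_pole

  tpl <- structure(list(mesh = NULL, landmarks = landmarks, latent = latent,
                        resolution = resolution, layout = layout,
                        faces = faces),
                   class = "humerus_template")
  inst <- instantiate_humerus(tpl, latent)
  tpl$mesh <- inst
  tpl$generator_info <- attr(inst, "generator_info")
  tpl
}

#' @method print humerus_template
#' @export
print.humerus_template <- function(x, ...) {
  cat(sprintf("humerus_template: resolution %.2f mm, %d vertices, %d faces\n",
              x$resolution, nrow(x$mesh$vertices), nrow(x$faces)))
  cat("  landmark sets:", paste(names(x$landmarks), collapse = ", "), "\n")
  invisible(x)
}

#' Instantiate a humerus mesh from latent parameters
#'
#' Recomputes the template vertex positions for a new latent vector, keeping
#' the topology (and therefore the dense correspondence and the landmark
#' indices) fixed. The generating head sphere, bone length and
#' mid-diaphysis section perimeter are recorded exactly in the
#' `generator_info` attribute for use as ground truth in validation.
#'
#' @param template a [build_template()] object.
#' @param latent a [humerus_latent()] (or named vector with the same
#'   fields).
#' @return a [surface_mesh()] with attribute `generator_info`.
#' @export
instantiate_humerus <- function(template, latent = template$latent) {
  validate_latent(latent)
  geo <- latent_geometry(latent)
  lay <- template$layout
  theta <- lay$theta
  n_theta <- lay$n_theta
  rings <- lay$rings

  z_gap <- lay$gap_frac * geo$L
  r_epi <- geo$ew / (2 * 1.55)
  z_delt <- geo$z_d1 + 0.5 * (geo$z_nb - geo$z_d1)
  sigma_z <- 0.1 * (geo$z_nb - geo$z_d1)
  dtheta_lat <- pmin(abs(theta - pi), 2 * pi - abs(theta - pi))
  theta_bump <- exp(-0.5 * (dtheta_lat / 0.55)^2)
  cos_t <- cos(theta); sin_t <- sin(theta)

  # the neck-shaft angle scales the articular-cap extent (a more valgus
  # head exposes more cap) in addition to shifting the head center; this
  # keeps the seven latent factors geometrically independent
  alpha0 <- template$latent[["neck_shaft_angle"]] * pi / 180
  alpha <- latent[["neck_shaft_angle"]] * pi / 180
  cap_fac <- 1 + 0.4 * (alpha - alpha0)
  psi_cap_eff <- lay$psi_cap * cap_fac
  z_cap_eff <- geo$z_h + geo$R * cos(psi_cap_eff)

  verts <- matrix(0, nrow(rings) * n_theta + 2L, 3L)
  info_perim <- NA_real_
  for (i in seq_len(nrow(rings))) {
    reg <- rings$region[i]; t <- rings$t[i]
    if (reg == "distal") {
      z <- z_gap + t * (geo$z_d1 - z_gap)
      bump <- exp(-0.5 * ((t - lay$t_e) / 0.18)^2)
      taper <- 0.25 + 0.75 * smoothstep(t / 0.22)
      r_base <- (geo$rs + (r_epi - geo$rs) * bump) * taper
      r <- r_base * (1 + 0.55 * bump * cos_t^2)
      xc <- 0
    } else if (reg == "shaft") {
      z <- geo$z_d1 + t * (geo$z_nb - geo$z_d1)
      r <- geo$rs + geo$dp * exp(-0.5 * ((z - z_delt) / sigma_z)^2) * theta_bump
      xc <- 0
    } else if (reg == "blend") {
      z <- geo$z_nb + t * (z_cap_eff - geo$z_nb)
      h <- smoothstep(t)
      r <- (1 - h) * geo$rs + h * geo$R * sin(psi_cap_eff)
      xc <- h * geo$x_h
    } else {                               # cap; t = 1 at cap base
      psi <- (lay$psi_top + t * (lay$psi_cap - lay$psi_top)) * cap_fac
      z <- geo$z_h + geo$R * cos(psi)
      r <- geo$R * sin(psi)
      xc <- geo$x_h
    }
    idx <- (i - 1L) * n_theta + seq_len(n_theta)
    verts[idx, 1] <- xc + r * cos_t
    verts[idx, 2] <- r * sin_t
    verts[idx, 3] <- z
    if (i == lay$i_delt) {
      ring <- verts[idx, , drop = FALSE]
      seg <- ring[c(seq_len(n_theta)[-1], 1L), ] - ring
      info_perim <- sum(sqrt(rowSums(seg^2)))
    }
  }
  verts[lay$bottom_pole, ] <- c(0, 0, 0)
  verts[lay$top_pole, ] <- c(geo$x_h, 0, geo$L)

  mesh <- surface_mesh(verts, template$faces)
  if (mesh_signed_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  attr(mesh, "generator_info") <- list(
    latent = latent,
    length = geo$L,
    head_center = c(geo$x_h, 0, geo$z_h),
    head_radius = geo$R,
    deltoid_level = z_delt,
    section_perimeter = info_perim)
  mesh
}

mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
      a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Population specification for the synthetic cohort
#'
#' Latents are drawn independently per field from normal distributions
#' truncated to the validity region of [humerus_latent()] (joint rejection
#' sampling). Default spreads emulate the variation of a healthy adult
#' population.
#'
#' @param n number of subjects (>= 2).
#' @param latent_means a [humerus_latent()] of mean values.
#' @param latent_sds named vector of per-field standard deviations (>= 0);
#'   fields missing from the vector get the defaults.
#' @param seed integer RNG seed.
#' @param template_resolution target mean edge length (mm) in `[0.5, 5]`.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(n, latent_means = humerus_latent(),
                            latent_sds = NULL, seed = 1L,
                            template_resolution = 1.5) {
  defaults <- c(length = 20, head_radius = 1.5, shaft_radius = 1,
                neck_shaft_angle = 4, head_offset = 1,
                deltoid_prominence = 0.4, epicondyle_width = 3)
  sds <- defaults
  if (!is.null(latent_sds)) {
    bad <- setdiff(names(latent_sds), latent_fields)
    if (length(bad)) stop("unknown latent field(s): ", paste(bad, collapse = ", "))
    sds[names(latent_sds)] <- latent_sds
  }
  if (any(sds < 0)) stop("latent sds must be non-negative")
  if (n < 2) stop("population size must be at least 2")
  if (template_resolution < 0.5 || template_resolution > 5)
    stop("template_resolution must lie in [0.5, 5] mm")
  validate_latent(latent_means)
  structure(list(n = as.integer(n), latent_means = latent_means,
                 latent_sds = sds, seed = as.integer(seed),
                 template_resolution = template_resolution),
            class = "population_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

draw_latent <- function(means, sds) {
  for (i in 1:1000) {
    lat <- stats::rnorm(length(latent_fields), means[latent_fields],
                        sds[latent_fields])
    names(lat) <- latent_fields
    if (latent_ok(lat)) return(lat)
  }
  stop("could not draw a valid latent (sds too large for the latent box?)")
}

#' Sample a corresponded synthetic humerus population
#'
#' @param spec a [population_spec()].
#' @param template optional pre-built [build_template()] at the spec's
#'   resolution (built on the fly when `NULL`).
#' @return list with elements `shapes` (a [shape_set()] of corresponded
#'   meshes), `latents` (data frame of the generating latents, one row per
#'   subject), and `template`.
#' @export
sample_population <- function(spec, template = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (is.null(template))
    template <- build_template(spec$template_resolution, spec$latent_means)
  lat_tab <- with_seed(spec$seed, {
    t(vapply(seq_len(spec$n),
             function(i) draw_latent(spec$latent_means, spec$latent_sds),
             numeric(length(latent_fields))))
  })
  colnames(lat_tab) <- latent_fields
  meshes <- lapply(seq_len(spec$n), function(i)
    instantiate_humerus(template, lat_tab[i, ]))
  list(shapes = shape_set(meshes, ids = sprintf("synth_%03d", seq_len(spec$n))),
       latents = as.data.frame(lat_tab), template = template)
}

#' Generate a bilateral (left/right) pair
#'
#' The left bone is instantiated from `latent`; the right bone is
#' instantiated from `latent` plus truncated-normal asymmetry noise and then
#' mirrored across the sagittal plane, emulating left-right asymmetry of a
#' healthy pair. With all asymmetry sds zero the pair is perfectly
#' mirrored.
#'
#' @param latent a [humerus_latent()].
#' @param asymmetry_sds named per-field sds of the left-right asymmetry
#'   (fields not named get 0).
#' @param seed integer RNG seed.
#' @param template a [build_template()] object.
#' @return list with `left` and `right` meshes and `latent_right`.
#' @export
generate_bilateral_pair <- function(latent, asymmetry_sds = NULL, seed = 1L,
                                    template) {
  validate_latent(latent)
  sds <- stats::setNames(numeric(length(latent_fields)), latent_fields)
  if (!is.null(asymmetry_sds)) {
    bad <- setdiff(names(asymmetry_sds), latent_fields)
    if (length(bad)) stop("unknown latent field(s): ", paste(bad, collapse = ", "))
    sds[names(asymmetry_sds)] <- asymmetry_sds
  }
  lat_right <- with_seed(seed, draw_latent(unclass(latent), sds))
  left <- instantiate_humerus(template, latent)
  right_unmirrored <- instantiate_humerus(template, lat_right)
  right <- mirror_mesh(right_unmirrored, plane3(c(0, 0, 0), c(1, 0, 0)))
  attr(right, "generator_info") <- attr(right_unmirrored, "generator_info")
  list(left = left, right = right, latent_right = lat_right)
}

#' A set of corresponded shapes sharing one topology
#'
#' @param shapes list of [surface_mesh()] objects or of n x 3 vertex
#'   matrices, all with the same vertex count.
#' @param faces shared face matrix; taken from the first mesh when `NULL`.
#' @param ids character labels, one per shape.
#' @return object of class `shape_set` with `vertices` (an N x 3 x M
#'   array), `faces` and `ids`.
#' @export
shape_set <- function(shapes, faces = NULL, ids = NULL) {
  stopifnot(is.list(shapes), length(shapes) >= 1L)
  get_v <- function(s) if (is_surface_mesh(s)) s$vertices else as.matrix(s)
  if (is.null(faces)) {
    if (!is_surface_mesh(shapes[[1]]))
      stop("faces must be given when shapes are bare vertex matrices")
    faces <- shapes[[1]]$faces
  }
  vl <- lapply(shapes, get_v)
  n <- nrow(vl[[1]])
  if (!all(vapply(vl, nrow, 1L) == n))
    stop("all shapes must have the same vertex count")
  arr <- array(unlist(vl), dim = c(n, 3L, length(vl)))
  if (is.null(ids)) ids <- sprintf("shape_%03d", seq_along(vl))
  structure(list(vertices = arr, faces = faces, ids = ids),
            class = "shape_set")
}

#' @method print shape_set
#' @export
print.shape_set <- function(x, ...) {
  cat(sprintf("shape_set: %d corresponded shapes, %d vertices each\n",
              dim(x$vertices)[3], dim(x$vertices)[1]))
  invisible(x)
}

#' @export
length.shape_set <- function(x) dim(x$vertices)[3]

#' Extract one shape of a set as a mesh
#' @param set a [shape_set()].
#' @param i shape index.
#' @return a [surface_mesh()].
#' @export
set_mesh <- function(set, i) {
  stopifnot(inherits(set, "shape_set"))
  surface_mesh(set$vertices[, , i], set$faces)
}

#' Flatten a shape set to an M x 3N matrix (one row per shape)
#'
#' Coordinates are concatenated column-major: all x, then all y, then all z.
#' @param x a [shape_set()].
#' @param ... unused.
#' @return numeric matrix with `length(x)` rows.
#' @method as.matrix shape_set
#' @export
as.matrix.shape_set <- function(x, ...) {
  d <- dim(x$vertices)
  m <- t(apply(x$vertices, 3, as.vector))
  dim(m) <- c(d[3], d[1] * 3L)
  rownames(m) <- x$ids
  m
}

vec_to_vertices <- function(v) matrix(v, ncol = 3L)
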