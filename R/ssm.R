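#' Fit a point-distribution statistical shape model
#'
#' The central model fit of the package. Given M aligned, corresponded
#' shapes, the model is the PCA decomposition of the vertex-coordinate
#' vectors: a shape is `S = mu + sum_i w_i * m_i`, with `mu` the mean
#' vector, `m_i` orthonormal modes of variation and `w_i` the per-mode
#' weights, which this package stores in standard-deviation units (the mm
#' scale lives in `mode_sds`). Shape variation is modelled as Gaussian,
#' `S ~ N(mu, Sigma)`, with `Sigma` diagonalized by the modes.
#'
#' The eigendecomposition uses the M x M Gram-matrix trick (the coordinate
#' dimension 3N is much larger than M), with sample-covariance divisor
#' `M - 1`. Modes with eigenvalues below `1e-12` of the largest are
#' discarded. Mode signs follow a fixed convention (the entry of largest
#' absolute value is positive) so fits are reproducible.
#'
#' When `measurements` is supplied, scalar measurements are appended to
#' each training vector (standardized to unit training sd and multiplied by
#' a balance factor) and the PCA is recomputed on the augmented vectors,
#' yielding an `augmented_shape_model` that can be conditioned on target
#' measurement values with [predict.augmented_shape_model()].
#'
#' @param shapes an aligned [shape_set()] (see [align_set()]); at least 2
#'   shapes (3 when augmenting with measurements).
#' @param measurements optional data frame of per-shape measurements (mm),
#'   one row per shape, e.g. columns `max_length`, `head_radius`,
#'   `shaft_circumference`.
#' @param which names of the measurement columns to include; defaults to
#'   all columns of `measurements`.
#' @param measurement_weight fraction of total augmented variance carried
#'   by the measurement block (balance factor). Conditioning constrains the
#'   block exactly, so results are insensitive to this over orders of
#'   magnitude; it only needs to keep the shape modes undistorted.
#' @return an object of class `shape_model` (and `augmented_shape_model`
#'   when measurements are included): list with `mean_vector`, `modes`
#'   (3N x K orthonormal), `mode_sds` (mm, non-increasing), `faces`,
#'   `n_vertices`, `n_training`, and for augmented models the measurement
#'   block bookkeeping.
#' @export
shape_model <- function(shapes, measurements = NULL, which = NULL,
                        measurement_weight = 0.01) {
  stopifnot(inherits(shapes, "shape_set"))
  x <- as.matrix(shapes)
  m <- nrow(x)
  if (m < 2L) stop("shape model needs at least 2 training shapes")
  n_coord <- ncol(x)

  meas_info <- NULL
  if (!is.null(measurements)) {
    if (m < 3L) stop("augmented model needs at least 3 training shapes")
    measurements <- as.data.frame(measurements)
    if (is.null(which)) which <- colnames(measurements)
    missing_cols <- setdiff(which, colnames(measurements))
    if (length(missing_cols))
      stop("missing measurement column(s): ", paste(missing_cols, collapse = ", "))
    z <- as.matrix(measurements[, which, drop = FALSE])
    if (nrow(z) != m) stop("one measurement row per shape is required")
    if (any(!is.finite(z))) stop("measurements must be finite")
    mu_z <- colMeans(z)
    sd_z <- apply(z, 2, stats::sd)
    if (any(sd_z == 0)) sd_z[sd_z == 0] <- 1   # zero-variance: carries no info
    # balance factor: measurement block ~ measurement_weight of total variance
    shape_var <- sum(apply(x, 2, stats::var))
    q <- length(which)
    gamma <- sqrt(measurement_weight / (1 - measurement_weight) * shape_var / q)
    scales <- rep(gamma, q)
    names(scales) <- which
    zs <- sweep(sweep(z, 2, mu_z), 2, sd_z / scales, "/")
    x <- cbind(x, zs)
    meas_info <- list(names = which, means = mu_z, sds = sd_z,
                      scales = scales)
  }

  mu <- unname(colMeans(x))
  xc <- sweep(x, 2, mu)
  dimnames(xc) <- NULL
  gram <- tcrossprod(xc)                 # M x M
  eg <- eigen(gram, symmetric = TRUE)
  lambda <- eg$values / (m - 1)
  keep <- lambda > 1e-12 * max(lambda, 0) & lambda > 0
  k <- sum(keep)
  if (k > 0) {
    modes <- crossprod(xc, eg$vectors[, keep, drop = FALSE])
    norms <- sqrt(colSums(modes^2))
    modes <- sweep(modes, 2, norms, "/")
    # sign convention: largest-magnitude entry positive
    flip <- vapply(seq_len(k), function(j) {
      i <- which.max(abs(modes[, j]))
      sign(modes[i, j])
    }, numeric(1))
    modes <- sweep(modes, 2, flip, "*")
    sds <- sqrt(lambda[keep])
  } else {
    modes <- matrix(0, ncol(x), 0)
    sds <- numeric(0)
  }

  obj <- structure(list(mean_vector = mu, modes = modes, mode_sds = sds,
                        faces = shapes$faces,
                        n_vertices = dim(shapes$vertices)[1],
                        n_training = m,
                        total_variance = sum(apply(x, 2, stats::var)),
                        measurement_block = meas_info),
                   class = "shape_model")
  if (!is.null(meas_info)) class(obj) <- c("augmented_shape_model", "shape_model")
  obj
}

# Rows of the augmented vector belonging to the shape / measurement block.
shape_rows <- function(model) seq_len(3L * model$n_vertices)
meas_rows <- function(model) {
  q <- length(model$measurement_block$names)
  3L * model$n_vertices + seq_len(q)
}

#' @method print shape_model
#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("shape_model: %d training shapes, %d vertices, %d modes\n",
              x$n_training, x$n_vertices, length(x$mode_sds)))
  if (inherits(x, "augmented_shape_model"))
    cat("  augmented with measurements:",
        paste(x$measurement_block$names, collapse = ", "), "\n")
  if (length(x$mode_sds)) {
    cc <- compactness(x)
    k95 <- modes_for_variance(x, 0.95)
    cat(sprintf("  %d mode(s) explain 95%% of the variance\n", k95))
    cat(sprintf("  first mode sd %.2f mm (%.1f%% of variance)\n",
                x$mode_sds[1], 100 * cc[1]))
  }
  invisible(x)
}

#' @method summary shape_model
#' @export
summary.shape_model <- function(object, ...) {
  cc <- compactness(object)
  out <- list(n_training = object$n_training,
              n_vertices = object$n_vertices,
              n_modes = length(object$mode_sds),
              mode_sds = object$mode_sds,
              cumulative_variance = cc,
              modes_95 = if (length(cc)) modes_for_variance(object, 0.95) else 0L,
              measurements = object$measurement_block$names)
  class(out) <- "summary.shape_model"
  out
}

#' @method print summary.shape_model
#' @export
print.summary.shape_model <- function(x, ...) {
  cat(sprintf("Point-distribution shape model (%d training shapes, %d vertices)\n",
              x$n_training, x$n_vertices))
  if (!is.null(x$measurements))
    cat("Measurement-augmented:", paste(x$measurements, collapse = ", "), "\n")
  cat(sprintf("%d retained modes; %d explain 95%% of the variance\n",
              x$n_modes, x$modes_95))
  if (x$n_modes) {
    tab <- data.frame(mode = seq_len(min(10L, x$n_modes)),
                      sd_mm = round(x$mode_sds[seq_len(min(10L, x$n_modes))], 3),
                      cum_var = round(x$cumulative_variance[seq_len(min(10L, x$n_modes))], 4))
    print(tab, row.names = FALSE)
    if (x$n_modes > 10L) cat("  ...\n")
  }
  invisible(x)
}

#' Compactness curve of a shape model
#'
#' Cumulative fraction of training variance explained by the first K
#' principal modes; the standard quality measure for how efficiently the
#' model encodes the population's shape variation.
#'
#' @param model a [shape_model()].
#' @return numeric vector of cumulative variance fractions (empty when the
#'   model retains no modes).
#' @export
compactness <- function(model) {
  stopifnot(inherits(model, "shape_model"))
  if (!length(model$mode_sds)) return(numeric(0))
  v <- model$mode_sds^2
  cumsum(v) / sum(v)
}

#' Number of modes needed to reach a variance fraction
#'
#' @param model a [shape_model()].
#' @param fraction target cumulative variance fraction in (0, 1].
#' @return the smallest number of leading modes whose cumulative variance
#'   fraction reaches `fraction`.
#' @export
modes_for_variance <- function(model, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  cc <- compactness(model)
  if (!length(cc)) return(0L)
  which(cc >= fraction - 1e-12)[1]
}

#' Synthesize a mesh from mode weights
#'
#' Evaluates `S = mu + sum_i w_i * sd_i * m_i` and reshapes the result into
#' a mesh on the model topology. Weights are in per-mode standard-deviation
#' units, so `weights = c(3, 0, 0, ...)` is the "+3 SD of mode 1" shape of
#' the usual mode-visualization convention.
#'
#' @param model a [shape_model()].
#' @param weights numeric vector of length K (defaults to all zero, the
#'   mean shape).
#' @return a [surface_mesh()].
#' @export
synthesize <- function(model, weights = numeric(length(model$mode_sds))) {
  stopifnot(inherits(model, "shape_model"))
  k <- length(model$mode_sds)
  if (length(weights) != k)
    stop("weights must have length ", k)
  v <- model$mean_vector
  if (k > 0)
    v <- v + as.numeric(model$modes %*% (weights * model$mode_sds))
  surface_mesh(vec_to_vertices(v[shape_rows(model)]), model$faces)
}

#' Project a corresponded shape into mode-weight space
#'
#' Inverse of [synthesize()]: `w_i = m_i . (x - mu) / sd_i`. The shape must
#' be on the model topology and aligned to the model frame. Modes with zero
#' sd get weight 0.
#'
#' @param model a [shape_model()].
#' @param shape a [surface_mesh()] or N x 3 vertex matrix on the model
#'   topology.
#' @return numeric vector of K weights in sd units.
#' @export
project_shape <- function(model, shape) {
  stopifnot(inherits(model, "shape_model"))
  v <- if (is_surface_mesh(shape)) shape$vertices else as.matrix(shape)
  if (nrow(v) != model$n_vertices)
    stop("shape is not on the model topology")
  x <- as.vector(v)
  if (inherits(model, "augmented_shape_model")) {
    # unaugmented geometry projected through the shape rows only
    d <- x - model$mean_vector[shape_rows(model)]
    w <- as.numeric(crossprod(model$modes[shape_rows(model), , drop = FALSE], d))
  } else {
    w <- as.numeric(crossprod(model$modes, x - model$mean_vector))
  }
  ifelse(model$mode_sds > 0, w / model$mode_sds, 0)
}

#' Draw random shapes from the model's Gaussian
#'
#' @param object a [shape_model()].
#' @param nsim number of shapes to draw.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of [surface_mesh()] objects.
#' @export
simulate.shape_model <- function(object, nsim = 1, seed = NULL, ...) {
  k <- length(object$mode_sds)
  draw <- function() synthesize(object, stats::rnorm(k))
  if (!is.null(seed)) with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
  else replicate(nsim, draw(), simplify = FALSE)
}

#' Plot the compactness curve
#'
#' @param x a [shape_model()].
#' @param fraction reference variance fraction drawn as a horizontal line.
#' @param ... passed to [graphics::plot()].
#' @export
plot.shape_model <- function(x, fraction = 0.95, ...) {
  cc <- compactness(x)
  if (!length(cc)) stop("model has no modes to plot")
  graphics::plot(seq_along(cc), 100 * cc, type = "b", pch = 16,
                 xlab = "number of modes",
                 ylab = "cumulative variance explained [%]",
                 ylim = c(0, 100), ...)
  graphics::abline(h = 100 * fraction, lty = 2)
  graphics::axis(3, at = modes_for_variance(x, fraction), labels = NA,
                 tcl = 0.3)
  invisible(x)
}

#' Serialize a shape model to a single archive file
#'
#' Layout (format version 1): one JSON header line holding the dimensions,
#' measurement bookkeeping and array byte counts, followed by the numeric
#' arrays (`mean_vector`, `modes`, `mode_sds`, `faces`) as little-endian
#' doubles/integers in the order announced by the header.
#'
#' @param model a [shape_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_shape_model <- function(model, path) {
  stopifnot(inherits(model, "shape_model"))
  header <- list(format = "humerusSSM-model", version = 1L,
                 n_vertices = model$n_vertices,
                 n_training = model$n_training,
                 n_coord = length(model$mean_vector),
                 n_modes = length(model$mode_sds),
                 n_faces = nrow(model$faces),
                 total_variance = model$total_variance,
                 measurement_block = model$measurement_block)
  con <- file(path, "wb")
  on.exit(close(con))
  hjson <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA)
  writeLines(as.character(hjson), con)
  writeBin(as.numeric(model$mean_vector), con, size = 8L, endian = "little")
  writeBin(as.numeric(model$modes), con, size = 8L, endian = "little")
  writeBin(as.numeric(model$mode_sds), con, size = 8L, endian = "little")
  writeBin(as.integer(model$faces), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a shape model written by [write_shape_model()]
#'
#' @param path file path.
#' @return a [shape_model()] (or `augmented_shape_model`).
#' @export
read_shape_model <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- jsonlite::fromJSON(readLines(con, n = 1L))
  if (!identical(header$format, "humerusSSM-model"))
    stop("not a shape-model archive: ", path)
  nc <- header$n_coord; nk <- header$n_modes; nf <- header$n_faces
  mu <- readBin(con, "numeric", nc, size = 8L, endian = "little")
  modes <- matrix(readBin(con, "numeric", nc * nk, size = 8L,
                          endian = "little"), nc, nk)
  sds <- readBin(con, "numeric", nk, size = 8L, endian = "little")
  faces <- matrix(readBin(con, "integer", nf * 3L, size = 4L,
                          endian = "little"), nf, 3L)
  mb <- header$measurement_block
  if (!is.null(mb)) {
    mb <- list(names = as.character(mb$names),
               means = stats::setNames(as.numeric(mb$means), mb$names),
               sds = stats::setNames(as.numeric(mb$sds), mb$names),
               scales = stats::setNames(as.numeric(mb$scales), mb$names))
  }
  obj <- structure(list(mean_vector = mu, modes = modes, mode_sds = sds,
                        faces = faces, n_vertices = header$n_vertices,
                        n_training = header$n_training,
                        total_variance = header$total_variance,
                        measurement_block = mb),
                   class = "shape_model")
  if (!is.null(mb)) class(obj) <- c("augmented_shape_model", "shape_model")
  obj
}
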