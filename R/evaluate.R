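#' Extract the proximal segment of a humerus
#'
#' Fits the diaphysis cylinder axis on the mid-shaft vertices, orients it
#' towards the (wider) proximal end, and cuts the bone with a plane normal
#' to that axis at `cut_distance` from the most proximal vertex, keeping
#' the proximal side. The cut is left uncapped. The default 60 mm segment
#' is the surgical region of interest in proximal humerus fractures.
#'
#' @param mesh a [surface_mesh()].
#' @param cut_distance distance of the cut from the most proximal point,
#'   measured along the diaphysis axis (mm).
#' @return the proximal segment as a [surface_mesh()].
#' @export
extract_proximal_segment <- function(mesh, cut_distance = 60) {
  stopifnot_mesh(mesh)
  axis <- diaphysis_axis(mesh)
  proj <- as.numeric(mesh$vertices %*% axis$direction)
  extent <- max(proj) - min(proj)
  if (cut_distance > extent + 1e-6)
    stop("cut distance exceeds the bone length")
  if (cut_distance >= extent) return(mesh)
  level <- max(proj) - cut_distance
  origin <- axis$direction * level
  cut_mesh_by_plane(mesh, plane3(origin, axis$direction), keep = "positive")
}

# Diaphysis axis oriented towards the proximal (head) end: cylinder fit on
# the mid-shaft band, sign chosen so the wider end is proximal (+).
diaphysis_axis <- function(mesh) {
  v <- mesh$vertices
  pc <- eigen(stats::cov(v), symmetric = TRUE)$vectors[, 1]
  proj <- as.numeric(v %*% pc)
  lo <- stats::quantile(proj, 0.30)
  hi <- stats::quantile(proj, 0.70)
  band <- v[proj >= lo & proj <= hi, , drop = FALSE]
  fit <- fit_cylinder_axis(band)
  u <- fit$direction
  proj <- as.numeric(v %*% u)
  qs <- stats::quantile(proj, c(0.15, 0.85))
  spread <- function(pts) {
    ctr <- colMeans(pts)
    d <- sweep(pts, 2, ctr)
    d <- d - outer(as.numeric(d %*% u), u)
    mean(sqrt(rowSums(d^2)))
  }
  low_end <- v[proj <= qs[1], , drop = FALSE]
  high_end <- v[proj >= qs[2], , drop = FALSE]
  if (spread(low_end) > spread(high_end)) u <- -u
  list(direction = u, fit = fit)
}

# Default segment template cache: the canonical generator humerus, cut at
# cut_distance, at a resolution tuned so the segment has ~n_points vertices.
.segment_template_cache <- new.env(parent = emptyenv())

default_segment_template <- function(n_points = 1952, cut_distance = 60) {
  key <- paste0(n_points, "_", cut_distance)
  hit <- .segment_template_cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- 2.0
  seg <- NULL
  for (i in 1:3) {
    tpl <- build_template(resolution = res)
    seg <- extract_proximal_segment(tpl$mesh, cut_distance)
    ratio <- nrow(seg$vertices) / n_points
    if (abs(ratio - 1) < 0.12) break
    res <- min(5, max(0.5, res * sqrt(ratio)))
  }
  assign(key, seg, envir = .segment_template_cache)
  seg
}

#' Establish correspondence between two proximal segments
#'
#' Warps a common segment template (by default the canonical template's
#' proximal segment with about `n_points` vertices) onto each segment, so
#' both are represented with an identical topology and vertex count.
#'
#' @param seg_a,seg_b proximal segment meshes, roughly aligned.
#' @param n_points target vertex count of the correspondence template.
#' @param segment_template optional explicit template mesh.
#' @param ... passed to [warp_template()].
#' @return list with `a` and `b` (warped [surface_mesh()] objects sharing
#'   one topology) and `faces`.
#' @export
correspond_segments <- function(seg_a, seg_b, n_points = 1952,
                                segment_template = NULL, ...) {
  if (is.null(segment_template))
    segment_template <- default_segment_template(n_points)
  wa <- warp_template(segment_template, seg_a, ...)
  wb <- warp_template(segment_template, seg_b, ...)
  list(a = wa, b = wb, faces = segment_template$faces)
}

#' Surface deviation map between two segments
#'
#' For every vertex of segment A, the signed distance to segment B's
#' surface (positive when A lies outside B, along B's outward normal at
#' the closest point). Absolute deviations are binned at the clinically
#' motivated 1 mm and 2 mm thresholds with area weighting (each vertex
#' carries one third of its incident triangle areas).
#'
#' @param seg_a a [surface_mesh()] whose vertices are evaluated.
#' @param seg_b a [surface_mesh()] acting as the reference surface.
#' @param thresholds increasing positive bin edges (mm).
#' @return object of class `deviation_map`: list with `signed` (per-vertex
#'   signed distances, mm), `summary` (named area fractions `lt1`,
#'   `b12`, `gt2` summing to 1), `max_abs`, `mean_signed` (area-weighted)
#'   and `thresholds`.
#' @export
deviation_map <- function(seg_a, seg_b, thresholds = c(1, 2)) {
  stopifnot_mesh(seg_a); stopifnot_mesh(seg_b)
  if (length(thresholds) != 2L || any(diff(thresholds) <= 0) ||
      any(thresholds <= 0))
    stop("thresholds must be two increasing positive values")
  m <- closest_points(seg_a$vertices, seg_b)
  nrm <- face_normals(seg_b)[m$face, , drop = FALSE]
  sgn <- sign(rowSums((seg_a$vertices - m$point) * nrm))
  sgn[sgn == 0] <- 1
  signed <- sgn * m$distance
  w <- vertex_areas(seg_a)
  w <- w / sum(w)
  a <- abs(signed)
  summary <- c(lt1 = sum(w[a < thresholds[1]]),
               b12 = sum(w[a >= thresholds[1] & a < thresholds[2]]),
               gt2 = sum(w[a >= thresholds[2]]))
  structure(list(signed = signed, summary = summary,
                 max_abs = max(a), mean_signed = sum(w * signed),
                 thresholds = thresholds),
            class = "deviation_map")
}

#' @method print deviation_map
#' @export
print.deviation_map <- function(x, ...) {
  cat("surface deviation map\n")
  cat(sprintf("  0-%g mm: %5.1f%%   %g-%g mm: %5.1f%%   >%g mm: %5.1f%%\n",
              x$thresholds[1], 100 * x$summary[["lt1"]],
              x$thresholds[1], x$thresholds[2], 100 * x$summary[["b12"]],
              x$thresholds[2], 100 * x$summary[["gt2"]]))
  cat(sprintf("  max |dev| %.2f mm, area-weighted mean signed dev %+.2f mm\n",
              x$max_abs, x$mean_signed))
  invisible(x)
}

# Shared pipeline: align candidate onto original, cut both, correspond,
# deviation map of the candidate relative to the original surface.
part_comparison <- function(original, candidate, segment_template,
                            cut_distance, n_points, thresholds = c(1, 2)) {
  tr <- icp_rigid(candidate, original)
  candidate <- apply_transform(tr, candidate)
  seg_o <- extract_proximal_segment(original, cut_distance)
  seg_c <- extract_proximal_segment(candidate, cut_distance)
  cs <- correspond_segments(seg_o, seg_c, n_points = n_points,
                            segment_template = segment_template)
  deviation_map(cs$b, cs$a, thresholds = thresholds)
}

#' Part comparison of an original humerus against a predicted one
#'
#' Rigidly aligns the predicted bone onto the original (no scaling),
#' extracts both proximal segments, establishes segment correspondence,
#' and computes the surface deviation of the prediction relative to the
#' original segment. Positive mean deviation means the prediction lies
#' outside the original (an overestimation).
#'
#' @param original ground-truth full humerus mesh.
#' @param predicted predicted full humerus mesh.
#' @param segment_template optional segment correspondence template.
#' @param cut_distance proximal segment length (mm).
#' @param n_points segment correspondence vertex count.
#' @param thresholds deviation bin edges (mm).
#' @return a [deviation_map()].
#' @export
compare_prediction <- function(original, predicted, segment_template = NULL,
                               cut_distance = 60, n_points = 1952,
                               thresholds = c(1, 2)) {
  if (is.null(segment_template))
    segment_template <- default_segment_template(n_points, cut_distance)
  part_comparison(original, predicted, segment_template, cut_distance,
                  n_points, thresholds)
}

#' Part comparison of a humerus against its mirrored contralateral
#'
#' Mirrors the contralateral (right) bone to the left and runs the same
#' cut/correspond/compare pipeline as [compare_prediction()], with the
#' mirrored bone in the role of the prediction. This is the
#' contralateral-registration baseline against which SSM predictions are
#' judged.
#'
#' @param left the original (left) humerus mesh.
#' @param right the contralateral (right) humerus mesh.
#' @inheritParams compare_prediction
#' @return a [deviation_map()].
#' @export
compare_contralateral <- function(left, right, segment_template = NULL,
                                  cut_distance = 60, n_points = 1952,
                                  thresholds = c(1, 2)) {
  if (is.null(segment_template))
    segment_template <- default_segment_template(n_points, cut_distance)
  mirrored <- mirror_mesh(right)
  part_comparison(left, mirrored, segment_template, cut_distance, n_points,
                  thresholds)
}

#' End-to-end synthetic validation experiment
#'
#' Builds a synthetic training cohort, fits the measurement-augmented shape
#' model, generates bilateral validation pairs, and evaluates the two
#' reconstruction arms per pair: the SSM prediction from the left bone's
#' measurements, and the mirrored contralateral bone. Reports per-specimen
#' deviation-bin fractions and their aggregate mean/sd per method.
#'
#' @param train_spec a [population_spec()] for the training cohort.
#' @param n_validation number of validation bilateral pairs.
#' @param asymmetry_sds named per-field left-right asymmetry sds (mm or
#'   degrees; see [generate_bilateral_pair()]).
#' @param which measurement subset used for conditioning (default the
#'   length + head-radius combination).
#' @param seed integer seed for the validation draws.
#' @param cut_distance proximal segment length (mm).
#' @param n_points segment correspondence vertex count.
#' @return object of class `validation_report`: list with `per_specimen`
#'   (data frame of bin fractions per pair and method), `aggregate` (mean
#'   and sd per bin per method, percent), `combination`, and the fitted
#'   `model`.
#' @export
run_validation_experiment <- function(train_spec, n_validation = 8,
                                      asymmetry_sds = c(shaft_radius = 0.4,
                                                        head_radius = 0.4,
                                                        length = 2,
                                                        head_offset = 0.4,
                                                        neck_shaft_angle = 1.5),
                                      which = c("max_length", "head_radius"),
                                      seed = 1L,
                                      cut_distance = 60, n_points = 1952) {
  pop <- sample_population(train_spec)
  template <- pop$template
  landmarks <- template$landmarks

  measurements <- measure_shape_set(pop$shapes, landmarks, which = which)
  aligned <- align_set(pop$shapes)
  model <- shape_model(aligned, measurements = measurements, which = which)

  segment_template <- extract_proximal_segment(
    synthesize(model), cut_distance)

  val_latents <- with_seed(seed + 1L, {
    t(vapply(seq_len(n_validation),
             function(i) draw_latent(train_spec$latent_means,
                                     train_spec$latent_sds),
             numeric(length(latent_fields))))
  })

  rows <- vector("list", n_validation)
  for (i in seq_len(n_validation)) {
    pair <- generate_bilateral_pair(
      structure(val_latents[i, ], class = "humerus_latent"),
      asymmetry_sds = asymmetry_sds, seed = seed + 100L + i,
      template = template)
    meas <- measure_all(pair$left, landmarks = landmarks, which = which)
    pred <- predict(model, as.data.frame(unclass(meas)))
    dm_ssm <- compare_prediction(pair$left, pred$mesh,
                                 segment_template = segment_template,
                                 cut_distance = cut_distance,
                                 n_points = n_points)
    dm_con <- compare_contralateral(pair$left, pair$right,
                                    segment_template = segment_template,
                                    cut_distance = cut_distance,
                                    n_points = n_points)
    rows[[i]] <- data.frame(
      specimen = rep(sprintf("pair_%02d", i), 2),
      method = c("ssm_prediction", "contralateral"),
      lt1 = c(dm_ssm$summary[["lt1"]], dm_con$summary[["lt1"]]),
      b12 = c(dm_ssm$summary[["b12"]], dm_con$summary[["b12"]]),
      gt2 = c(dm_ssm$summary[["gt2"]], dm_con$summary[["gt2"]]),
      max_abs = c(dm_ssm$max_abs, dm_con$max_abs),
      mean_signed = c(dm_ssm$mean_signed, dm_con$mean_signed))
  }
  per_specimen <- do.call(rbind, rows)

  agg <- do.call(rbind, lapply(split(per_specimen, per_specimen$method),
                               function(d) {
    data.frame(method = d$method[1],
               bin = c("0-1 mm", "1-2 mm", ">2 mm"),
               mean_pct = 100 * c(mean(d$lt1), mean(d$b12), mean(d$gt2)),
               sd_pct = 100 * c(stats::sd(d$lt1), stats::sd(d$b12),
                                stats::sd(d$gt2)))
  }))
  rownames(agg) <- NULL

  structure(list(per_specimen = per_specimen, aggregate = agg,
                 combination = which, model = model,
                 n_validation = n_validation),
            class = "validation_report")
}

#' @method print validation_report
#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation experiment: %d bilateral pairs, conditioning on %s\n",
              x$n_validation, paste(x$combination, collapse = " + ")))
  cat("Percent of proximal segment surface area per deviation bin:\n")
  tab <- x$aggregate
  tab$mean_pct <- sprintf("%.1f%%", tab$mean_pct)
  tab$sd_pct <- sprintf("(SD %.1f%%)", tab$sd_pct)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Export a deviation map as a colored point set (PLY with scalar quality)
#'
#' Writes segment A's vertices with the signed deviation as a `quality`
#' property, for inspection in standard mesh viewers.
#'
#' @param map a [deviation_map()].
#' @param mesh the segment mesh the map was computed on (vertex order must
#'   match).
#' @param path output PLY path.
#' @return `path`, invisibly.
#' @export
write_deviation_ply <- function(map, mesh, path) {
  stopifnot(inherits(map, "deviation_map"))
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property double x", "property double y", "property double z",
               "property double quality",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g %.6g", v[, 1], v[, 2], v[, 3],
                     map$signed), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}
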