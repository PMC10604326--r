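#' Predict a full humerus shape from measurement values
#'
#' The core prediction pathway: given an `augmented_shape_model` (a shape
#' model whose training vectors carried scalar measurements, see
#' [shape_model()]), setting target values for the measurements determines
#' a conditional shape. The conditional mean of the joint Gaussian is
#' computed as the minimum-Mahalanobis-norm mode-weight vector subject to
#' the measurement rows of `mu + sum w_i sd_i m_i` matching the scaled
#' targets: `w = B' (B B' + eps I)^-1 t` with `B` the measurement rows of
#' the sd-scaled mode matrix and ridge `eps = 1e-8` for numerical safety
#' with correlated measurements. This coincides with the Schur-complement
#' conditional mean whenever the measurement sub-covariance is nonsingular.
#'
#' Targets far outside the training range (more than 5 training sds from
#' the training mean) set the `out_of_range` flag in the result rather
#' than raising an error: fracture cases may legitimately sit at
#' population extremes.
#'
#' @param object an `augmented_shape_model`.
#' @param newdata named list, vector or one-row data frame with a target
#'   value (mm) for each of the model's measurements.
#' @param ridge ridge added to the constraint normal matrix.
#' @param ... unused.
#' @return object of class `ssm_prediction`: list with `mesh` (the
#'   predicted [surface_mesh()]), `weights_used` (mode weights, sd units),
#'   `achieved_measurements` (measurement block of the predicted vector,
#'   mm), `conditioning_residual` (distance between target and achieved
#'   block in scaled units), `targets` and `out_of_range`.
#' @export
predict.augmented_shape_model <- function(object, newdata, ridge = 1e-8, ...) {
  mb <- object$measurement_block
  if (is.data.frame(newdata)) {
    if (nrow(newdata) != 1L) stop("newdata must describe a single bone")
    newdata <- as.list(newdata[1, , drop = FALSE])
  }
  targets <- unlist(newdata)
  missing_m <- setdiff(mb$names, names(targets))
  if (length(missing_m))
    stop("missing target measurement(s): ", paste(missing_m, collapse = ", "))
  extra <- setdiff(names(targets), mb$names)
  if (length(extra))
    stop("measurement(s) not in the model: ", paste(extra, collapse = ", "))
  targets <- targets[mb$names]
  if (any(!is.finite(targets))) stop("targets must be finite")

  z_sd <- abs(targets - mb$means) / mb$sds
  out_of_range <- any(z_sd > 5)

  t_scaled <- (targets - mb$means) / mb$sds * mb$scales
  k <- length(object$mode_sds)
  rows_m <- meas_rows(object)
  b <- object$modes[rows_m, , drop = FALSE] *
    rep(object$mode_sds, each = length(rows_m))
  # the measurement block was centred before PCA, so its mean rows are ~0
  rhs <- t_scaled - object$mean_vector[rows_m]
  gram <- tcrossprod(b) + diag(ridge, length(rows_m))
  w <- as.numeric(crossprod(b, solve(gram, rhs)))

  vec <- object$mean_vector +
    if (k > 0) as.numeric(object$modes %*% (w * object$mode_sds)) else 0
  achieved_scaled <- vec[rows_m]
  achieved <- achieved_scaled / mb$scales * mb$sds + mb$means
  mesh <- surface_mesh(vec_to_vertices(vec[shape_rows(object)]), object$faces)

  structure(list(mesh = mesh,
                 weights_used = w,
                 achieved_measurements = stats::setNames(achieved, mb$names),
                 conditioning_residual = sqrt(sum((achieved_scaled - t_scaled)^2)),
                 targets = stats::setNames(as.numeric(targets), mb$names),
                 out_of_range = out_of_range),
            class = "ssm_prediction")
}

#' @method print ssm_prediction
#' @export
print.ssm_prediction <- function(x, ...) {
  cat("SSM prediction from measurements\n")
  tab <- data.frame(target = x$targets,
                    achieved = x$achieved_measurements)
  print(round(tab, 3))
  cat(sprintf("conditioning residual %.3g (scaled units)%s\n",
              x$conditioning_residual,
              if (x$out_of_range) "; WARNING: targets outside training range (>5 sd)" else ""))
  invisible(x)
}

#' Measure every shape of a corresponded set
#'
#' Applies the anatomical measurement operators to each shape of a
#' corresponded set, propagating the template landmarks (valid for every
#' shape because the topology is shared).
#'
#' @param shapes a [shape_set()].
#' @param landmarks template landmark list (see [build_template()]).
#' @param which measurements to take, a subset of `c("max_length",
#'   "head_radius", "shaft_circumference")`.
#' @return data frame with one row per shape.
#' @export
measure_shape_set <- function(shapes, landmarks,
                              which = c("max_length", "head_radius",
                                        "shaft_circumference")) {
  stopifnot(inherits(shapes, "shape_set"))
  rows <- lapply(seq_len(length(shapes)), function(i) {
    mesh <- set_mesh(shapes, i)
    as.data.frame(unclass(measure_all(mesh, landmarks = landmarks,
                                       which = which)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- shapes$ids
  out
}

#' Compare prediction accuracy across measurement combinations
#'
#' Builds one measurement-augmented model per combination of the three
#' geometric parameters (all seven non-empty subsets by default), predicts
#' each test humerus from its own measured values, and evaluates the
#' proximal-segment part comparison. Reported per combination: mean and sd
#' of the percentage of segment surface area deviating by more than 2 mm,
#' and of the maximum absolute deviation.
#'
#' @param train_shapes aligned training [shape_set()].
#' @param train_measurements data frame of training measurements (columns
#'   `max_length`, `head_radius`, `shaft_circumference`).
#' @param test_meshes list of ground-truth test meshes.
#' @param test_measurements data frame of their measured parameter values.
#' @param combinations list of character vectors naming the measurement
#'   subsets to test; default all 7 non-empty subsets.
#' @param segment_template segment template mesh for correspondence (see
#'   [correspond_segments()]); built from the canonical generator template
#'   when `NULL`.
#' @param cut_distance proximal segment length (mm).
#' @param n_points target segment correspondence vertex count.
#' @return data frame with one row per combination and columns
#'   `combination`, `mean_pct_gt2`, `sd_pct_gt2`, `mean_max_dev`,
#'   `sd_max_dev`.
#' @export
evaluate_combinations <- function(train_shapes, train_measurements,
                                  test_meshes, test_measurements,
                                  combinations = NULL,
                                  segment_template = NULL,
                                  cut_distance = 60, n_points = 1952) {
  all_m <- c("max_length", "head_radius", "shaft_circumference")
  if (is.null(combinations)) {
    combinations <- unlist(lapply(1:3, function(k)
      utils::combn(all_m, k, simplify = FALSE)), recursive = FALSE)
  }
  if (is.null(segment_template))
    segment_template <- default_segment_template(n_points, cut_distance)
  rows <- lapply(combinations, function(combo) {
    model <- shape_model(train_shapes, measurements = train_measurements,
                         which = combo)
    pct2 <- numeric(length(test_meshes))
    maxd <- numeric(length(test_meshes))
    for (i in seq_along(test_meshes)) {
      pred <- predict(model, test_measurements[i, combo, drop = FALSE])
      dm <- compare_prediction(test_meshes[[i]], pred$mesh,
                               segment_template = segment_template,
                               cut_distance = cut_distance,
                               n_points = n_points)
      pct2[i] <- 100 * dm$summary[["gt2"]]
      maxd[i] <- dm$max_abs
    }
    data.frame(combination = paste(combo, collapse = "+"),
               mean_pct_gt2 = mean(pct2), sd_pct_gt2 = stats::sd(pct2),
               mean_max_dev = mean(maxd), sd_max_dev = stats::sd(maxd))
  })
  do.call(rbind, rows)
}
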