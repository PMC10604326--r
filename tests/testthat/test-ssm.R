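test_that("degenerate and low-rank populations are decomposed exactly", {
  tpl <- test_template(5)
  ident <- shape_set(lapply(1:5, function(i) tpl$mesh))
  m0 <- shape_model(ident)
  expect_equal(length(m0$mode_sds), 0L)
  expect_equal(vec_mesh <- synthesize(m0)$vertices, tpl$mesh$vertices,
               tolerance = 1e-12)
  expect_length(compactness(m0), 0)

  # two latent factors, noiseless: two modes reach 99.9% variance
  pop <- sample_population(
    population_spec(25, latent_sds = sds_zero_except("length", "head_radius"),
                    seed = 42, template_resolution = 5),
    template = tpl)
  model <- shape_model(pop$shapes)
  cc <- compactness(model)
  expect_gte(cc[2], 0.999)
  # the length factor dominates the variance; the second mode is needed
  # only at a fraction beyond its share
  expect_equal(modes_for_variance(model, 0.9995), 2L)
  expect_lte(modes_for_variance(model, 0.95), 2L)
  expect_equal(modes_for_variance(model, 1.0), length(model$mode_sds))

  expect_error(shape_model(shape_set(list(tpl$mesh))), "at least 2")
})

test_that("the Gram-matrix trick matches the direct covariance eigendecomposition", {
  set.seed(11)
  n <- 40   # vertices; 3N = 120 coordinates, M = 8 shapes
  faces <- cbind(1:(n - 2), 2:(n - 1), 3:n)
  shapes <- lapply(1:8, function(i) matrix(rnorm(3 * n, sd = 3), n, 3))
  ss <- shape_set(shapes, faces = faces)
  model <- shape_model(ss)

  x <- t(vapply(shapes, as.vector, numeric(3 * n)))
  cov_direct <- stats::cov(x)
  eg <- eigen(cov_direct, symmetric = TRUE)
  k <- length(model$mode_sds)
  expect_equal(model$mode_sds^2, eg$values[seq_len(k)], tolerance = 1e-8)
  # modes agree up to sign
  for (j in seq_len(k)) {
    dots <- abs(sum(model$modes[, j] * eg$vectors[, j]))
    expect_equal(dots, 1, tolerance = 1e-8)
  }
  # trace conservation: eigenvalue sum equals total coordinate variance
  expect_equal(sum(model$mode_sds^2), sum(diag(cov_direct)), tolerance = 1e-8)
})

test_that("synthesis and projection are mutually inverse", {
  tpl <- test_template(5)
  # factors with an exactly linear action, so the model is full rank and
  # the PCA reconstruction identity holds to numerical precision
  pop <- sample_population(
    population_spec(10, latent_sds = sds_zero_except(
      "length", "head_radius", "shaft_radius", "head_offset",
      "deltoid_prominence", "epicondyle_width"), seed = 5,
      template_resolution = 5), template = tpl)
  model <- shape_model(pop$shapes)
  k <- length(model$mode_sds)

  expect_equal(synthesize(model)$vertices,
               matrix(model$mean_vector, ncol = 3), tolerance = 1e-12)
  expect_equal(project_shape(model, synthesize(model)), rep(0, k),
               tolerance = 1e-10)
  set.seed(6)
  w <- rnorm(k)
  expect_equal(project_shape(model, synthesize(model, w)), w,
               tolerance = 1e-8)
  # training shapes are reconstructed through the model (full rank here)
  for (i in c(1, 7)) {
    rec <- synthesize(model, project_shape(model, set_mesh(pop$shapes, i)))
    expect_lt(max(abs(rec$vertices - pop$shapes$vertices[, , i])), 1e-6)
  }
  # training projections have unit per-mode sd (weights in sd units)
  w_train <- vapply(seq_len(length(pop$shapes)), function(i)
    project_shape(model, set_mesh(pop$shapes, i)), numeric(k))
  expect_equal(apply(w_train, 1, stats::sd), rep(1, k), tolerance = 1e-6)
  expect_error(synthesize(model, rep(0, k + 2)), "length")
})

test_that("compactness is monotone, terminal at one, and order-invariant", {
  tpl <- test_template(5)
  pop <- sample_population(
    population_spec(12, seed = 8, template_resolution = 5), template = tpl)
  model <- shape_model(pop$shapes)
  cc <- compactness(model)
  expect_true(all(diff(cc) >= -1e-15))
  expect_equal(cc[length(cc)], 1, tolerance = 1e-12)

  perm <- c(4, 1, 12, 7, 3, 9, 2, 11, 6, 10, 5, 8)
  shuffled <- shape_set(lapply(perm, function(i) set_mesh(pop$shapes, i)))
  model_p <- shape_model(shuffled)
  expect_equal(model_p$mode_sds, model$mode_sds, tolerance = 1e-10)
  for (j in seq_along(model$mode_sds))
    expect_equal(abs(sum(model_p$modes[, j] * model$modes[, j])), 1,
                 tolerance = 1e-8)

  # reconstruction error decreases monotonically with the mode count
  x <- set_mesh(pop$shapes, 3)
  w <- project_shape(model, x)
  errs <- vapply(seq_along(w), function(kk) {
    wk <- w; wk[-seq_len(kk)] <- 0
    sqrt(sum((synthesize(model, wk)$vertices - x$vertices)^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("models serialize to the archive format and back", {
  tpl <- test_template(5)
  pop <- sample_population(
    population_spec(6, seed = 4, template_resolution = 5), template = tpl)
  meas <- measure_shape_set(pop$shapes, tpl$landmarks,
                            which = c("max_length", "head_radius"))
  model <- shape_model(align_set(pop$shapes), measurements = meas)
  path <- withr::local_tempfile(fileext = ".ssm")
  write_shape_model(model, path)
  back <- read_shape_model(path)
  expect_s3_class(back, "augmented_shape_model")
  expect_equal(back$mean_vector, model$mean_vector)
  expect_equal(back$modes, model$modes)
  expect_equal(back$mode_sds, model$mode_sds)
  expect_equal(back$measurement_block$means, model$measurement_block$means)
  # a conditioned prediction goes through the deserialized model unchanged
  targ <- as.list(model$measurement_block$means)
  p1 <- predict(model, targ)
  p2 <- predict(back, targ)
  expect_equal(p2$mesh$vertices, p1$mesh$vertices, tolerance = 1e-12)
})
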