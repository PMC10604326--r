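# shared small training setup: 2 free latent factors, measurements are
# noiseless functions of them
prediction_fixture <- function() {
  cached("pred_fixture", function() {
    tpl <- test_template(5)
    pop <- sample_population(
      population_spec(40, latent_sds = sds_zero_except("length", "head_radius"),
                      seed = 30, template_resolution = 5),
      template = tpl)
    meas <- measure_shape_set(pop$shapes, tpl$landmarks,
                              which = c("max_length", "head_radius"))
    list(tpl = tpl, pop = pop, meas = meas,
         model = shape_model(align_set(pop$shapes), measurements = meas))
  })
}

test_that("augmenting with measurements preserves the shape modes", {
  fx <- prediction_fixture()
  plain <- shape_model(align_set(fx$pop$shapes))
  # zero-variance measurement adds no information: shape modes unchanged
  const_meas <- data.frame(max_length = rep(300, length(fx$pop$shapes)))
  aug0 <- shape_model(align_set(fx$pop$shapes), measurements = const_meas)
  k <- min(length(plain$mode_sds), length(aug0$mode_sds))
  sr <- humerusSSM:::shape_rows(aug0)
  for (j in seq_len(k)) {
    dot <- abs(sum(aug0$modes[sr, j] * plain$modes[, j]))
    expect_equal(dot, 1, tolerance = 1e-6)
  }
  expect_equal(aug0$mode_sds[seq_len(k)], plain$mode_sds[seq_len(k)],
               tolerance = 1e-8)
  # measurement block of the mean vector holds the (centred) training means
  mr <- humerusSSM:::meas_rows(fx$model)
  expect_lt(max(abs(fx$model$mean_vector[mr])), 1e-9)
})

test_that("conditioning at the training mean returns the mean shape", {
  fx <- prediction_fixture()
  mb <- fx$model$measurement_block
  pred <- predict(fx$model, as.list(mb$means))
  expect_lt(max(abs(pred$mesh$vertices - synthesize(fx$model)$vertices)), 1e-6)
  expect_false(pred$out_of_range)
})

test_that("conditioning equals the closed-form joint-Gaussian conditional mean", {
  set.seed(7)
  n <- 20; m <- 12
  faces <- cbind(1:(n - 2), 2:(n - 1), 3:n)
  shapes <- lapply(seq_len(m), function(i)
    matrix(rnorm(n * 3, sd = 2), n, 3) + matrix(rnorm(3), n, 3, byrow = TRUE))
  ss <- shape_set(shapes, faces = faces)
  meas <- data.frame(
    max_length = vapply(shapes, function(v) max(v[, 1]), numeric(1)),
    head_radius = vapply(shapes, function(v) mean(v[, 2]), numeric(1)))
  am <- shape_model(ss, measurements = meas)
  targ <- c(max_length = 0.9 * meas$max_length[1] + 0.1 * mean(meas$max_length),
            head_radius = meas$head_radius[2])
  pred <- predict(am, targ)

  # independent Schur-complement oracle on the raw training covariance
  x <- t(vapply(shapes, as.vector, numeric(3 * n)))
  mb <- am$measurement_block
  z <- sweep(sweep(as.matrix(meas), 2, mb$means), 2, mb$sds / mb$scales, "/")
  aug <- cbind(x, z)
  cc <- stats::cov(aug)
  ix <- seq_len(3 * n); iz <- 3 * n + 1:2
  tz <- (targ - mb$means) / mb$sds * mb$scales
  mu <- colMeans(aug)
  cond <- mu[ix] + cc[ix, iz] %*% solve(cc[iz, iz], tz - mu[iz])
  expect_lt(max(abs(as.vector(pred$mesh$vertices) - cond)), 1e-6)
})

test_that("in-sample conditioning is exact and deterministic", {
  fx <- prediction_fixture()
  targ <- as.list(fx$meas[3, ])
  p1 <- predict(fx$model, targ)
  expect_lt(p1$conditioning_residual, 1e-6)
  expect_lt(max(abs(p1$achieved_measurements - unlist(targ))), 1e-6)
  p2 <- predict(fx$model, targ)
  expect_identical(p1$mesh$vertices, p2$mesh$vertices)
})

test_that("predictions recover held-out bones from two noiseless parameters", {
  fx <- prediction_fixture()
  tpl <- fx$tpl
  set.seed(77)
  for (rep in 1:2) {
    lat <- unclass(tpl$latent)
    lat["length"] <- lat["length"] + rnorm(1, sd = 20)
    lat["head_radius"] <- lat["head_radius"] + rnorm(1, sd = 1.5)
    held <- instantiate_humerus(tpl, lat)
    meas_h <- measure_all(held, landmarks = tpl$landmarks,
                          which = c("max_length", "head_radius"))
    pred <- predict(fx$model, as.data.frame(unclass(meas_h)))
    # compare corresponded vertices after removing pose
    tr <- humerusSSM:::kabsch(pred$mesh$vertices, held$vertices)
    pv <- apply_transform(tr, pred$mesh$vertices)
    err <- sqrt(rowSums((pv - held$vertices)^2))
    expect_lt(stats::quantile(err, 0.99), 0.5)
  }
})

test_that("conditioning is insensitive to the measurement balance factor", {
  fx <- prediction_fixture()
  targ <- list(max_length = 320, head_radius = 23)
  meshes <- lapply(c(0.001, 0.01, 0.1), function(wgt) {
    mdl <- shape_model(align_set(fx$pop$shapes), measurements = fx$meas,
                       measurement_weight = wgt)
    predict(mdl, targ)$mesh$vertices
  })
  expect_lt(max(abs(meshes[[1]] - meshes[[2]])), 1e-6)
  expect_lt(max(abs(meshes[[3]] - meshes[[2]])), 1e-6)
})

test_that("out-of-range targets warn through the flag, not an error", {
  fx <- prediction_fixture()
  mb <- fx$model$measurement_block
  far <- as.list(mb$means + 8 * mb$sds)
  pred <- predict(fx$model, far)
  expect_true(pred$out_of_range)
  expect_error(predict(fx$model, list(max_length = 300)), "missing target")
  expect_error(predict(fx$model, list(max_length = 300, head_radius = 24,
                                      bogus = 1)), "not in the model")
})

test_that("the seven-combination table has the expected structure", {
  tpl <- test_template(5)
  pop <- sample_population(population_spec(25, seed = 61,
                                           template_resolution = 5),
                           template = tpl)
  meas <- measure_shape_set(pop$shapes, tpl$landmarks)
  aligned <- align_set(pop$shapes)
  set.seed(8)
  test_lat <- humerusSSM:::draw_latent(unclass(tpl$latent), population_sds)
  held <- instantiate_humerus(tpl, test_lat)
  meas_h <- as.data.frame(unclass(measure_all(held, landmarks = tpl$landmarks)))
  tab <- evaluate_combinations(aligned, meas, list(held), meas_h,
                               segment_template = test_segment_template(800),
                               n_points = 800)
  expect_equal(nrow(tab), 7L)
  expect_setequal(colnames(tab), c("combination", "mean_pct_gt2", "sd_pct_gt2",
                                   "mean_max_dev", "sd_max_dev"))
  expect_true("max_length+head_radius" %in% tab$combination)
  expect_true(all(tab$mean_pct_gt2 >= 0 & tab$mean_pct_gt2 <= 100))
})
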