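test_that("the humeral coordinate system is orthonormal, anchored and equivariant", {
  tpl <- test_template(4)
  m <- tpl$mesh
  lm <- tpl$landmarks
  hcs <- build_hcs(m, lm)
  gi <- attr(m, "generator_info")
  expect_lt(sqrt(sum((hcs$origin - gi$head_center)^2)), 0.1)
  g <- cbind(hcs$x_axis, hcs$y_axis, hcs$z_axis)
  expect_lt(max(abs(crossprod(g) - diag(3))), 1e-9)
  expect_equal(humerusSSM:::cross3(hcs$x_axis, hcs$y_axis), hcs$z_axis,
               tolerance = 1e-9)
  # y points proximally (towards the head)
  expect_gt(sum(hcs$y_axis * c(0, 0, 1)), 0.9)

  set.seed(12)
  tr <- random_rigid()
  h2 <- build_hcs(apply_transform(tr, m), lm)
  expect_equal(h2$origin, as.numeric(apply_transform(tr, rbind(hcs$origin))),
               tolerance = 1e-6)
  expect_equal(h2$y_axis, as.numeric(tr$rotation %*% hcs$y_axis),
               tolerance = 1e-6)
})

test_that("measurements recover the generating latent parameters", {
  tpl <- test_template(4)
  set.seed(21)
  for (i in 1:4) {
    lat <- humerusSSM:::draw_latent(unclass(tpl$latent), population_sds)
    m <- instantiate_humerus(tpl, lat)
    gi <- attr(m, "generator_info")
    lm <- tpl$landmarks
    hcs <- build_hcs(m, lm)
    expect_equal(measure_max_length(m, hcs), gi$length, tolerance = 0.5)
    expect_equal(measure_head_radius(m, lm), gi$head_radius, tolerance = 0.1)
    circ <- measure_shaft_circumference(m, hcs, lm)
    expect_lt(abs(circ / gi$section_perimeter - 1), 0.01)
  }
  # factor isolation: the head radius ignores shaft girth
  lat2 <- unclass(tpl$latent)
  lat2["shaft_radius"] <- lat2["shaft_radius"] + 2
  m2 <- instantiate_humerus(tpl, lat2)
  expect_equal(measure_head_radius(m2, tpl$landmarks),
               unclass(tpl$latent)[["head_radius"]], tolerance = 0.1)
})

test_that("measurements are rigid-invariant and scale-equivariant", {
  tpl <- test_template(4)
  m <- tpl$mesh
  lm <- tpl$landmarks
  hcs <- build_hcs(m, lm)
  len <- measure_max_length(m, hcs)
  rad <- measure_head_radius(m, lm)
  circ <- measure_shaft_circumference(m, hcs, lm)

  set.seed(14)
  tr <- random_rigid()
  mt <- apply_transform(tr, m)
  ht <- build_hcs(mt, lm)
  expect_lt(abs(measure_max_length(mt, ht) / len - 1), 1e-6)
  expect_lt(abs(measure_head_radius(mt, lm) / rad - 1), 1e-6)
  expect_lt(abs(measure_shaft_circumference(mt, ht, lm) / circ - 1), 1e-6)

  ms <- surface_mesh(1.1 * m$vertices, m$faces)
  hs <- build_hcs(ms, lm)
  expect_lt(abs(measure_max_length(ms, hs) / (1.1 * len) - 1), 1e-6)
  expect_lt(abs(measure_head_radius(ms, lm) / (1.1 * rad) - 1), 1e-6)
  expect_lt(abs(measure_shaft_circumference(ms, hs, lm) / (1.1 * circ) - 1), 1e-6)
})

test_that("the section perimeter of a perfect cylinder is 2 pi r", {
  cyl <- cylinder_mesh(r = 10, h = 100, n_theta = 48)
  # synthetic frame: long axis z, section through mid-height
  hcs <- structure(list(origin = c(0, 0, 100), x_axis = c(1, 0, 0),
                        y_axis = c(0, 0, 1), z_axis = c(0, -1, 0),
                        head_radius = NA), class = "humeral_cs")
  lm <- list(deltoid_tuberosity = which.min(abs(cyl$vertices[, 3] - 50))[1])
  circ <- measure_shaft_circumference(cyl, hcs, lm)
  expect_lt(abs(circ / (2 * pi * 10) - 1), 0.005)
})

test_that("measurement subsets behave as requested", {
  tpl <- test_template(4)
  lm <- tpl$landmarks
  two <- measure_all(tpl$mesh, landmarks = lm,
                     which = c("max_length", "head_radius"))
  expect_named(two, c("max_length", "head_radius"))
  all3 <- measure_all(tpl$mesh, landmarks = lm)
  expect_named(all3, c("max_length", "head_radius", "shaft_circumference"))
  expect_error(measure_all(tpl$mesh, landmarks = lm, which = character(0)),
               "at least one")
})

test_that("the ICC matches two-way ANOVA arithmetic", {
  # identical replicates
  expect_equal(icc(c(10, 12, 14, 16), c(10, 12, 14, 16)), 1.0)

  # hand-checkable 4-subject example against a direct ANOVA computation
  r1 <- c(9, 11, 14, 16)
  r2 <- c(10, 11.5, 13.5, 16.5)
  val <- icc(r1, r2)
  d <- data.frame(y = c(r1, r2),
                  subj = factor(rep(1:4, 2)),
                  sess = factor(rep(1:2, each = 4)))
  ms <- summary(stats::aov(y ~ subj + sess, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  oracle <- (msr - mse) / (msr + mse + 2 / 4 * (msc - mse))
  expect_equal(val, oracle, tolerance = 1e-10)

  # dominating noise drives the ICC towards zero
  set.seed(99)
  subj <- rnorm(200, sd = 1)
  expect_lt(icc(subj + rnorm(200, sd = 10), subj + rnorm(200, sd = 10)), 0.2)

  expect_warning(z <- icc(rep(5, 6), rep(5, 6)), "between-subject")
  expect_equal(z, 0)
  expect_error(icc(1:2, 1:2), "at least 3")
})
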