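test_that("template construction yields the advertised structure", {
  tpl <- cached("tpl_1.5", function() build_template(1.5))
  expect_gte(nrow(tpl$mesh$vertices), 1500)
  lm <- tpl$landmarks
  expect_true(all(vapply(lm, length, 1L) > 0))
  # anatomically disjoint sets do not share vertices
  singles <- lm[c("epicondyle_medial_caudal", "epicondyle_lateral_caudal",
                  "trochlea_inferior", "head_superior", "deltoid_tuberosity")]
  expect_equal(anyDuplicated(unlist(singles)), 0L)
  expect_false(any(unlist(singles[1:3]) %in% lm$articular_surface))
  # head apex is the extreme point of the long axis
  expect_equal(which.max(tpl$mesh$vertices[, 3]), lm$head_superior)
  # articular vertices lie on the generating head sphere
  gi <- tpl$generator_info
  art <- tpl$mesh$vertices[lm$articular_surface, ]
  res <- sqrt(rowSums(sweep(art, 2, gi$head_center)^2)) - gi$head_radius
  expect_lt(max(abs(res)), 1e-6)
  # resolution control
  expect_error(build_template(0.2), "resolution")
  expect_error(build_template(7), "resolution")
})

test_that("mean edge length tracks the requested resolution", {
  for (res in c(1.5, 4)) {
    tpl <- test_template(res)
    if (res == 1.5) tpl <- cached("tpl_1.5", function() build_template(1.5))
    e <- mean_edge_length(tpl$mesh)
    expect_gt(e, 0.65 * res)
    expect_lt(e, 1.35 * res)
  }
})

test_that("instantiation is the identity at the template latent and deterministic", {
  tpl <- test_template(4)
  m1 <- instantiate_humerus(tpl, tpl$latent)
  expect_lt(max(abs(m1$vertices - tpl$mesh$vertices)), 1e-9)
  lat <- unclass(tpl$latent) + c(12, 1, -0.5, 2, 0.5, 0.2, -2)
  a <- instantiate_humerus(tpl, lat)
  b <- instantiate_humerus(tpl, lat)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$faces, tpl$mesh$faces)
  expect_error(instantiate_humerus(tpl, unclass(tpl$latent) * c(1, 0, 1, 1, 1, 1, 1)),
               "positive")
})

test_that("latent factors act independently on the geometry", {
  tpl <- test_template(4)
  lat2 <- unclass(tpl$latent)
  lat2["length"] <- 2 * lat2[["length"]]
  m2 <- instantiate_humerus(tpl, lat2)
  expect_equal(diff(range(m2$vertices[, 3])), 620, tolerance = 0.5)
  # head sphere untouched by the length change
  gi <- attr(m2, "generator_info")
  fit <- fit_sphere(m2$vertices[tpl$landmarks$articular_surface, ])
  expect_equal(fit$radius, gi$head_radius, tolerance = 0.1)
  # distinct latents produce distinct meshes (injectivity spot check)
  base <- tpl$mesh$vertices
  for (fld in names(population_sds)) {
    lat <- unclass(tpl$latent)
    lat[fld] <- lat[fld] + population_sds[fld]
    mi <- instantiate_humerus(tpl, lat)
    expect_gt(max(sqrt(rowSums((mi$vertices - base)^2))), 0.1)
  }
})

test_that("population sampling is reproducible and statistically calibrated", {
  spec <- population_spec(100, seed = 9, template_resolution = 5)
  tpl <- test_template(5)
  p1 <- sample_population(spec, template = tpl)
  p2 <- sample_population(spec, template = tpl)
  expect_identical(p1$latents, p2$latents)
  # law of large numbers: sample mean within 3 sd/sqrt(n)
  for (fld in names(population_sds)) {
    if (population_sds[fld] == 0) next
    expect_lt(abs(mean(p1$latents[[fld]]) - unclass(tpl$latent)[fld]),
              3 * population_sds[fld] / sqrt(100))
  }
  # degenerate population: all sds zero gives identical meshes
  spec0 <- population_spec(5, latent_sds = sds_zero_except(), seed = 1,
                           template_resolution = 5)
  p0 <- sample_population(spec0, template = tpl)
  expect_lt(max(abs(p0$shapes$vertices[, , 1] - p0$shapes$vertices[, , 5])), 1e-12)
  expect_error(population_spec(1), "at least 2")
  expect_error(population_spec(10, latent_sds = c(bogus = 1)), "unknown")
})

test_that("bilateral pairs mirror exactly at zero asymmetry", {
  tpl <- test_template(4)
  pair <- generate_bilateral_pair(tpl$latent, NULL, seed = 3, template = tpl)
  back <- mirror_mesh(pair$right)
  expect_lt(max(abs(back$vertices - pair$left$vertices)), 1e-9)
  # asymmetry restricted to the shaft leaves the head radii equal
  pair2 <- generate_bilateral_pair(tpl$latent,
                                   c(shaft_radius = 0.5), seed = 4,
                                   template = tpl)
  r_l <- attr(pair2$left, "generator_info")$head_radius
  r_r <- attr(pair2$right, "generator_info")$head_radius
  expect_lt(abs(r_l - r_r), 0.1)
  # seeded reproducibility
  pair3 <- generate_bilateral_pair(tpl$latent, c(shaft_radius = 0.5),
                                   seed = 4, template = tpl)
  expect_identical(pair2$latent_right, pair3$latent_right)
})

test_that("shape sets flatten consistently and round-trip meshes", {
  tpl <- test_template(5)
  spec <- population_spec(4, seed = 2, template_resolution = 5)
  pop <- sample_population(spec, template = tpl)
  x <- as.matrix(pop$shapes)
  expect_equal(dim(x), c(4, 3 * nrow(tpl$mesh$vertices)))
  expect_equal(matrix(x[2, ], ncol = 3), pop$shapes$vertices[, , 2])
  m2 <- set_mesh(pop$shapes, 2)
  expect_equal(m2$vertices, pop$shapes$vertices[, , 2])
  expect_error(shape_set(list(tpl$mesh, tetra_mesh())), "same vertex count")
})
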