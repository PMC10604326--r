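test_that("proximal segments are cut at the requested axial extent", {
  tpl <- test_template(4)
  m <- tpl$mesh
  seg <- extract_proximal_segment(m, 60)
  ax <- humerusSSM:::diaphysis_axis(m)
  pr <- as.numeric(seg$vertices %*% ax$direction)
  expect_equal(max(pr) - min(pr), 60, tolerance = 1.0)
  # the whole articular surface lies within the segment
  art <- m$vertices[tpl$landmarks$articular_surface, ]
  expect_lt(max(closest_points(art, seg)$distance), 1e-9)
  # cutting at the full bone length keeps the whole mesh
  full_len <- diff(range(as.numeric(m$vertices %*% ax$direction)))
  expect_equal(nrow(extract_proximal_segment(m, full_len)$faces),
               nrow(m$faces))
  expect_error(extract_proximal_segment(m, full_len + 5), "exceeds")
})

test_that("deviation maps honor their analytic oracles", {
  seg <- cached("seg_15", function()
    extract_proximal_segment(cached("tpl_1.5",
                                    function() build_template(1.5))$mesh, 60))
  # self-comparison: the zero map
  dm0 <- deviation_map(seg, seg)
  expect_equal(dm0$summary[["lt1"]], 1, tolerance = 1e-12)
  expect_equal(dm0$max_abs, 0)

  # uniform 1.5 mm outward offset lands in the 1-2 mm bin, A inside B
  infl <- surface_mesh(seg$vertices + 1.5 * vertex_normals(seg), seg$faces)
  dm1 <- deviation_map(seg, infl)
  expect_gt(dm1$summary[["b12"]], 0.95)
  expect_equal(dm1$mean_signed, -1.5, tolerance = 0.05)

  # concentric spheres 24 vs 27 mm: all deviation 3 mm, beyond 2 mm
  s24 <- uv_sphere_mesh(24)
  s27 <- uv_sphere_mesh(27)
  dm2 <- deviation_map(s24, s27)
  expect_equal(dm2$summary[["gt2"]], 1, tolerance = 1e-12)
  expect_equal(dm2$max_abs, 3, tolerance = 0.03)
  expect_equal(abs(dm2$mean_signed), 3, tolerance = 0.03)

  # bin fractions always sum to one
  for (dm in list(dm0, dm1, dm2))
    expect_equal(sum(dm$summary), 1, tolerance = 1e-9)
  expect_error(deviation_map(seg, seg, thresholds = c(2, 1)), "increasing")
})

test_that("an inflated candidate yields a positive (overestimation) deviation", {
  tpl <- test_template(4)
  lat_fat <- unclass(tpl$latent)
  lat_fat["shaft_radius"] <- lat_fat["shaft_radius"] + 1.5
  lat_fat["head_radius"] <- lat_fat["head_radius"] + 1.5
  fat <- instantiate_humerus(tpl, lat_fat)
  dm <- compare_prediction(tpl$mesh, fat,
                           segment_template = test_segment_template(800),
                           n_points = 800)
  expect_gt(dm$mean_signed, 0)
})

test_that("a perfectly mirrored pair compares as identical", {
  tpl <- test_template(4)
  pair <- generate_bilateral_pair(tpl$latent, NULL, seed = 3, template = tpl)
  dm <- compare_contralateral(pair$left, pair$right,
                              segment_template = test_segment_template(800),
                              n_points = 800)
  expect_gt(dm$summary[["lt1"]], 0.999)
  expect_lt(dm$max_abs, 0.1)
  expect_equal(sum(dm$summary), 1, tolerance = 1e-9)
})

test_that("segment correspondence outputs share the template topology", {
  tpl <- test_template(4)
  st <- test_segment_template(800)
  seg_a <- extract_proximal_segment(tpl$mesh, 60)
  lat_b <- unclass(tpl$latent)
  lat_b["head_radius"] <- lat_b["head_radius"] + 1
  seg_b <- extract_proximal_segment(instantiate_humerus(tpl, lat_b), 60)
  cs <- correspond_segments(seg_a, seg_b, segment_template = st)
  expect_identical(cs$a$faces, st$faces)
  expect_identical(cs$b$faces, st$faces)
  expect_equal(nrow(cs$a$vertices), nrow(st$vertices))
  # identical inputs correspond identically
  cs2 <- correspond_segments(seg_a, seg_a, segment_template = st)
  expect_lt(max(abs(cs2$a$vertices - cs2$b$vertices)), 0.1)
})

test_that("deviation maps export as PLY with a quality channel", {
  seg <- extract_proximal_segment(test_template(4)$mesh, 60)
  dm <- deviation_map(seg, seg)
  path <- withr::local_tempfile(fileext = ".ply")
  write_deviation_ply(dm, seg, path)
  txt <- readLines(path, n = 12)
  expect_true(any(grepl("property double quality", txt)))
  expect_equal(nrow(read_mesh(path)$vertices), nrow(seg$vertices))
})
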