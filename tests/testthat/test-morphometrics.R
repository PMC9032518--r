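test_that("gyrification index of convex shapes is 1; star polygons are exact", {
  gi <- gyrification_index(mesh_disk(20, 2))
  expect_equal(gi$mean, 1, tolerance = 0.01)
  expect_gte(gi$mean, 1 - 1e-9)
  # 12-pointed star: expected ratio from direct edge-length arithmetic
  n <- 12
  ang <- pi * (seq_len(2 * n) - 1) / n
  r <- ifelse(seq_len(2 * n) %% 2 == 1, 10, 4)
  star <- cbind(r * cos(ang), r * sin(ang))
  edge <- sqrt(10^2 + 4^2 - 2 * 10 * 4 * cos(pi / n))
  hull_edge <- sqrt(2 * 10^2 * (1 - cos(2 * pi / n)))
  expect_equal(polygon_gyrification_index(star), (2 * n * edge) / (n * hull_edge),
               tolerance = 1e-12)
})

test_that("reference GI-age curve reproduces its published landmarks", {
  expect_equal(round(cao_reference_gi(40), 1), 2.8)
  expect_equal(round(cao_reference_gi(80), 1), 2.6)
  expect_equal(cao_reference_gi(85), 3.4 - 0.175 * log(85 - 2.9991), tolerance = 1e-12)
  expect_equal(round(cao_reference_gi(85), 2), 2.63)
  expect_error(cao_reference_gi(2), "age")
})

test_that("two-way nearest-node thickness: concentric circles and parallel lines", {
  th_ang <- seq(0, 2 * pi, length.out = 721)[-721]
  outer <- cbind(20 * cos(th_ang), 20 * sin(th_ang))
  inner <- cbind(17 * cos(th_ang), 17 * sin(th_ang))
  tm <- cortical_thickness(outer, inner)
  expect_equal(tm$mean, 3, tolerance = 0.2)   # node spacing ~0.17 mm
  xs <- seq(0, 50, by = 0.5)
  a_ <- cbind(xs, 0); b_ <- cbind(xs, 2.4)
  tm2 <- cortical_thickness(a_, b_)
  expect_equal(unique(round(tm2$thickness, 10)), 2.4)
  expect_error(cortical_thickness(a_[1:2, ], b_), "degenerate")
})

test_that("accelerated nearest-neighbor search equals the quadratic oracle", {
  set.seed(77)
  for (d in 2:3) {
    q <- matrix(runif(300 * d, -10, 10), ncol = d)
    r <- matrix(runif(1000 * d, -10, 10), ncol = d)
    expect_identical(atrophysim:::nn_index(q, r), atrophysim:::nn_index_brute(q, r))
  }
  # thickness map via both paths is identical
  set.seed(78)
  p1 <- matrix(runif(200 * 2), ncol = 2)
  p2 <- matrix(runif(300 * 2), ncol = 2)
  expect_equal(cortical_thickness(p1, p2)$thickness,
               cortical_thickness(p1, p2, brute = TRUE)$thickness)
})

test_that("volume fractions: analytic start, unit brain sum, denominator labels", {
  m <- coarse_phantom()
  res <- run_simulation(m, default_materials(),
                        simulation_config(t_end = 1, dt = 0.5, mode = "healthy"))
  areas <- region_measures(m)
  fr0 <- volume_fractions(res, step = 1, denominator = "brain")
  expect_equal(unname(fr0[tissue_labels()]),
               unname(areas[tissue_labels()] / sum(areas[tissue_labels()])),
               tolerance = 1e-12)
  for (s in seq_along(res$times)) {
    fb <- volume_fractions(res, s, "brain")
    expect_equal(sum(fb[tissue_labels()]), 1, tolerance = 1e-10)
    fi <- volume_fractions(res, s, "intracranial")
    expect_equal(sum(fi), 1, tolerance = 1e-10)
    expect_lt(sum(fi[tissue_labels()]), 1)
  }
  expect_identical(attr(volume_fractions(res), "denominator"), "brain")
})

test_that("sulcal widening: zero at zero displacement, unknown names rejected", {
  m <- coarse_phantom()
  res <- run_simulation(m, default_materials(),
                        simulation_config(t_end = 0, dt = 0.5, mode = "healthy"))
  sw <- sulcal_widening(res)
  expect_true(all(sw$pct_change == 0))
  expect_setequal(unique(sw$sulcus), names(m$sulci))
  expect_error(sulcal_widening(res, "rolandic"), "sylvian")
})

test_that("morphometry report: zero-span run has no changes; metrics are rigid-invariant", {
  m <- coarse_phantom()
  res0 <- run_simulation(m, default_materials(),
                         simulation_config(t_end = 0, dt = 0.5, mode = "healthy"))
  rep0 <- build_report(res0)
  expect_equal(rep0$ventricular_expansion_factor, 1)
  expect_equal(unname(rep0$hippocampal_fraction_change_pct), c(0, 0))
  expect_equal(rep0$gi$young$mean, rep0$gi$aged$mean)
  # rigid motion of mesh + displacements leaves all metrics unchanged
  res <- run_simulation(m, default_materials(),
                        simulation_config(t_end = 1, dt = 0.5, mode = "healthy"))
  rep1 <- build_report(res)
  ang <- 0.7
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  shift <- c(13, -4)
  m2 <- m
  m2$nodes <- sweep(m$nodes %*% t(R), 2, -shift)
  res2 <- res
  res2$mesh <- m2
  res2$u_final <- res$u_final %*% t(R)
  rep2 <- build_report(res2)
  expect_equal(rep2$gi$young$mean, rep1$gi$young$mean, tolerance = 1e-10)
  expect_equal(rep2$gi$aged$mean, rep1$gi$aged$mean, tolerance = 1e-10)
  expect_equal(rep2$thickness$young$mean, rep1$thickness$young$mean, tolerance = 1e-10)
  expect_equal(rep2$thickness$aged$mean, rep1$thickness$aged$mean, tolerance = 1e-10)
})

test_that("3D slice-wise GI: a cylinder-like slab is convex in every slice", {
  dsk <- mesh_disk(20, 4)
  slab <- extrude_mesh(dsk, n_layers = 2, dz = 4)
  # rasterized contours carry a staircase bias of a few percent, the same
  # bias a binary-image pipeline has; the ratio must still be near 1
  gp <- gyrification_index(slab, n_slices = 5, axis = 3, pixel = 0.5)
  expect_true(all(is.na(gp$gi) | abs(gp$gi - 1) < 0.1))
  expect_gte(sum(!is.na(gp$gi)), 3L)
})

test_that("report serialization writes CSV and JSON artifacts", {
  m <- coarse_phantom()
  res <- run_simulation(m, default_materials(),
                        simulation_config(t_end = 1, dt = 0.5, mode = "healthy"))
  rep <- build_report(res)
  dir <- tempfile()
  files <- write_report(rep, dir)
  expect_true(all(file.exists(file.path(dir, c("morphometry_healthy.csv",
                                               "morphometry_healthy.json")))))
  long <- read.csv(file.path(dir, "morphometry_healthy.csv"))
  expect_true(all(c("time", "metric", "item", "value") %in% names(long)))
  js <- jsonlite::read_json(file.path(dir, "morphometry_healthy.json"))
  expect_equal(js$ventricular_expansion_factor, rep$ventricular_expansion_factor,
               tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
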