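test_that("reference state is already in equilibrium", {
  m <- coarse_phantom()
  sol <- solve_equilibrium(m, theta = 1, default_materials())
  expect_identical(sol$iterations, 0L)
  expect_equal(max(abs(sol$u)), 0)
})

test_that("a single unconstrained element shrinks stress-free to J = theta", {
  m1 <- labeled_mesh(rbind(c(0, 0), c(2, 0), c(0, 2)), rbind(c(1, 2, 3)), "WM",
                     boundary_sets = list(csf_outer = 1L))
  sol <- solve_equilibrium(m1, theta = 0.8, default_materials(), dirichlet = NULL,
                           pin_dofs = c(1L, 2L, 4L), tol = 1e-12)
  Jd <- atrophysim:::element_measures(m1, m1$nodes + sol$u) /
    atrophysim:::element_measures(m1)
  expect_equal(Jd, 0.8, tolerance = 1e-8)
  F <- diag(2) * sqrt(Jd)
  st <- cauchy_stress_and_tangent(F, 0.8, 2, 64.67)
  expect_lt(max(abs(st$sigma)), 1e-8)
})

test_that("uniform shrink of an annulus with a fixed rim expands the cavity", {
  ann <- mesh_annulus(10, 30, 2)
  sol <- solve_equilibrium(ann, theta = 0.9, default_materials(), tol = 1e-9)
  ib <- ann$boundary_sets$cavity
  Xd <- ann$nodes + sol$u
  o <- order(atan2(ann$nodes[ib, 2], ann$nodes[ib, 1]))
  cav <- atrophysim:::polygon_signed_area(Xd[ib[o], 1], Xd[ib[o], 2])
  expect_gt(cav, pi * 100)
})

test_that("healthy-mode atrophy follows the closed-form linear decay", {
  m <- coarse_phantom()
  res <- run_simulation(m, default_materials(),
                        simulation_config(t_end = 4, dt = 0.1, mode = "healthy"))
  reg <- m$region
  expect_equal(max(abs(res$theta_final[reg == 1] - (1 - 0.0015 * 4))), 0,
               tolerance = 1e-12)
  expect_equal(max(abs(res$theta_final[reg %in% 2:3] - (1 - 0.001 * 4))), 0,
               tolerance = 1e-12)
  expect_true(all(res$theta_final[reg %in% 4:5] == 1))
  expect_null(res$c_final)
})

test_that("t_end = 0 returns only the initial state", {
  m <- coarse_phantom()
  res <- run_simulation(m, default_materials(),
                        simulation_config(t_end = 0, dt = 0.1, mode = "healthy"))
  expect_identical(length(res$times), 1L)
  expect_equal(max(abs(res$u_final)), 0)
  expect_true(all(res$theta_final == 1))
})

test_that("a mirror-symmetric problem yields a mirror-symmetric displacement field", {
  # crossed-diagonal strip: mesh exactly symmetric about its horizontal
  # midline, so the solution symmetry is limited only by solver tolerance
  m <- mesh_strip(40, 10, 2, crossed = TRUE)
  sol <- solve_equilibrium(m, theta = 0.9, default_materials(),
                           dirichlet = m$boundary_sets$left, tol = 1e-11)
  mirr <- cbind(m$nodes[, 1], 10 - m$nodes[, 2])
  idx <- atrophysim:::nn_index_brute(mirr, m$nodes)
  expect_lt(max(atrophysim:::row_norms(m$nodes[idx, ] - mirr)), 1e-9)
  u <- sol$u
  asym <- abs(u[idx, 1] - u[, 1]) + abs(u[idx, 2] + u[, 2])
  expect_lt(max(asym), 1e-7 * max(abs(u)))
})

test_that("halving the time step changes the final displacement field by < 1%", {
  m <- coarse_phantom()
  r1 <- run_simulation(m, default_materials(),
                       simulation_config(t_end = 2, dt = 0.2, mode = "healthy"))
  r2 <- run_simulation(m, default_materials(),
                       simulation_config(t_end = 2, dt = 0.1, mode = "healthy"))
  rel <- sqrt(sum((r1$u_final - r2$u_final)^2)) / sqrt(sum(r2$u_final^2))
  expect_lt(rel, 0.01)
})

test_that("volume series: initial volumes at zero displacement, ventricle grows", {
  m <- coarse_phantom()
  res <- run_simulation(m, default_materials(),
                        simulation_config(t_end = 2, dt = 0.5, mode = "healthy"))
  vs <- region_volume_series(res)
  expect_equal(unname(vs[1, -1]), as.data.frame(t(region_measures(m)[region_labels()])),
               ignore_attr = TRUE)
  expect_true(all(diff(vs$VENT) > 0))
  expect_true(all(diff(rowSums(vs[, c("WM", "GM", "HIPPO")])) < 0))
})

test_that("the dimension-agnostic solver runs on a quasi-3D slab", {
  # two element layers so the mid sheet of nodes is free to move
  m3 <- build_brain_phantom(phantom_params(target_edge_length = 7, dimension = 3,
                                           slab_layers = 2))
  res <- run_simulation(m3, default_materials(),
                        simulation_config(t_end = 1, dt = 0.5, mode = "healthy"))
  expect_true(all(is.finite(res$u_final)))
  expect_equal(max(abs(res$theta_final[m3$region == 1] - (1 - 0.0015))), 0,
               tolerance = 1e-12)
  # deformed volumes stay positive and tissue loses volume
  expect_true(all(res$volumes[, tissue_labels()] > 0))
  expect_lt(sum(res$volumes[3, c("WM", "GM", "HIPPO")]),
            sum(res$volumes[1, c("WM", "GM", "HIPPO")]))
})

test_that("Newton failure reporting names the step and suggests substepping", {
  m1 <- labeled_mesh(rbind(c(0, 0), c(2, 0), c(0, 2)), rbind(c(1, 2, 3)), "WM",
                     boundary_sets = list(csf_outer = 1L))
  expect_error(
    solve_equilibrium(m1, 0.8, default_materials(), dirichlet = NULL,
                      pin_dofs = c(1L, 2L, 4L), tol = 1e-12, max_iter = 1),
    "substepping")
})
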