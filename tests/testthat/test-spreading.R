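test_that("kinetic reparameterization reproduces the logistic growth rate", {
  expect_equal(kinetic_alpha(k0 = 0.09, k1 = 1, k1_tilde = 0, k12 = 1), 0.09)
  expect_equal(kinetic_alpha(k0 = 3, k1 = 6, k1_tilde = 1, k12 = 2), 0)
  expect_equal(kinetic_alpha(k0 = 0.4, k1 = 0.8, k1_tilde = 0.05, k12 = 0.5), 0.2)
  expect_error(kinetic_alpha(k0 = 1, k1 = 0, k1_tilde = 0, k12 = 1), "k1")
})

test_that("logistic reaction term and its fixed points", {
  a <- 0.09
  r0 <- reaction_term(0, a)
  expect_equal(r0$f, 0); expect_equal(r0$df_dc, a)
  r1 <- reaction_term(1, a)
  expect_equal(r1$f, 0); expect_equal(r1$df_dc, -a)
  rh <- reaction_term(0.5, a)
  expect_equal(rh$f, 0.0225); expect_equal(rh$df_dc, 0)
})

test_that("closed-form logistic oracle hits its landmarks", {
  expect_equal(closed_form_logistic(0.3, 0.09, 0), 0.3)
  expect_equal(closed_form_logistic(0.5, 0.09, 1e4), 1, tolerance = 1e-12)
  t_half <- log(7 / 3) / 0.09
  expect_equal(closed_form_logistic(0.3, 0.09, t_half), 0.5, tolerance = 1e-12)
})

test_that("seeding sets exactly the seed-region-incident nodes", {
  m <- coarse_phantom()
  f <- seed_concentration(m, spreading_params())
  hip_nodes <- sort(unique(as.vector(
    m$elements[m$region == match("HIPPO", region_labels()), ])))
  expect_setequal(which(f$values == 0.3), hip_nodes)
  expect_true(all(f$values[-hip_nodes] == 0))
  f0 <- seed_concentration(m, spreading_params(c0_seed = 0))
  expect_true(all(f0$values == 0))
  expect_error(seed_concentration(mesh_disk(10, 3), spreading_params()), "HIPPO")
})

test_that("disjoint seed-region components are all seeded", {
  m <- coarse_phantom()
  # relabel a far-away WM element as a second HIPPO component
  ctr <- atrophysim:::element_centroids(m)
  wm <- which(m$region == match("WM", region_labels()))
  far <- wm[which.max(ctr[wm, 2])]   # topmost WM element, far from the crescent
  m$region[far] <- match("HIPPO", region_labels())
  f <- seed_concentration(m, spreading_params())
  expect_true(all(f$values[m$elements[far, ]] == 0.3))
})

test_that("uniform and saturated states are invariant; bounds are preserved", {
  m <- mesh_disk(15, 3)
  sp <- spreading_params()
  op <- atrophysim:::fk_operator(m, sp)
  f0 <- concentration_field(rep(0, nrow(m$nodes)))
  f1 <- concentration_field(rep(1, nrow(m$nodes)))
  for (k in 1:5) {
    f0 <- step_concentration(f0, m, sp, 0.5, op = op)
    f1 <- step_concentration(f1, m, sp, 0.5, op = op)
  }
  expect_equal(max(abs(f0$values)), 0)
  expect_equal(max(abs(f1$values - 1)), 0, tolerance = 1e-12)
  set.seed(11)
  f <- concentration_field(runif(nrow(m$nodes)))
  for (dt in c(0.1, 0.5, 1)) {
    f <- step_concentration(f, m, sp, dt, op = op)
    expect_true(all(f$values >= 0 & f$values <= 1))
  }
})

test_that("uniform field follows the closed-form logistic", {
  m <- mesh_disk(15, 3)
  sp <- spreading_params()
  op <- atrophysim:::fk_operator(m, sp)
  f <- concentration_field(rep(0.3, nrow(m$nodes)))
  err <- 0
  for (k in 1:200) {
    f <- step_concentration(f, m, sp, 0.05, op = op)
    err <- max(err, max(abs(f$values - closed_form_logistic(0.3, 0.09, k * 0.05))))
  }
  expect_lt(err, 1e-3)
})

test_that("no diffusive exchange into zero-diffusivity regions", {
  # seeded phantom: ventricle and CSF have d = 0 and start at c = 0 except
  # nodes shared with the seed; interior fluid nodes must stay at 0
  m <- coarse_phantom()
  sp <- spreading_params()
  f <- seed_concentration(m, sp)
  op <- atrophysim:::fk_operator(m, sp)
  csf_el <- m$region == match("CSF", region_labels())
  tissue_el <- m$region %in% match(tissue_labels(), region_labels())
  csf_only <- setdiff(unique(as.vector(m$elements[csf_el, ])),
                      unique(as.vector(m$elements[tissue_el, ])))
  for (k in 1:20) f <- step_concentration(f, m, sp, 0.5, op = op)
  expect_equal(max(f$values[csf_only]), 0)
  expect_gt(max(f$values), 0.2)  # tissue keeps evolving
})
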