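test_that("material table defaults carry the reference parameter set", {
  mat <- default_materials()
  expect_identical(rownames(mat), c("WM", "GM", "HIPPO", "VENT", "CSF"))
  expect_equal(mat["WM", ],
               data.frame(row.names = "WM", lambda = 64.67, mu = 2, G_h = 0.0015,
                          G_c = 0.0035, c_crit = 0.5, d = 15, alpha = 0.09),
               ignore_attr = TRUE)
  expect_equal(unname(unlist(mat["GM", c("lambda", "mu", "G_h", "G_c")])),
               c(32.33, 1, 0.001, 0.002))
  expect_equal(mat["HIPPO", c("lambda", "mu")], mat["GM", c("lambda", "mu")],
               ignore_attr = TRUE)
  expect_equal(unname(unlist(mat["VENT", c("lambda", "mu")])), c(29.77, 15.34))
  expect_equal(unname(unlist(mat["CSF", c("lambda", "mu")])), c(7.22, 14.43))
  expect_true(all(is.na(mat[c("VENT", "CSF"), "G_h"])))
  expect_equal(unname(mat$d), c(15, 15, 15, 0, 0))
  expect_error(material_table(data.frame(lambda = 1)), "columns")
  bad <- default_materials(); bad["WM", "mu"] <- -1
  expect_error(material_table(bad), "mu")
})

test_that("smooth Heaviside activation: midpoint, symmetry, monotonicity", {
  expect_equal(smooth_heaviside(0.5, 0.5, 50), 0.5)
  expect_equal(smooth_heaviside(0.6, 0.5, 50), 1 / (1 + exp(-5)), tolerance = 1e-12)
  expect_equal(smooth_heaviside(0.4, 0.5, 50), 1 - 1 / (1 + exp(-5)), tolerance = 1e-12)
  cs <- seq(0, 1, by = 0.01)
  expect_true(all(diff(smooth_heaviside(cs, 0.5, 50)) > 0))
})

test_that("atrophy rate interpolates between healthy and accelerated limits", {
  mat <- default_materials()
  expect_equal(atrophy_rate(0, mat, "WM"), 0.0015, tolerance = 1e-8)
  expect_equal(atrophy_rate(1, mat, "WM"), 0.005, tolerance = 1e-8)
  expect_equal(atrophy_rate(0.5, mat, "GM"), 0.001 + 0.5 * 0.002)
  expect_equal(atrophy_rate(0.7, mat, "VENT"), 0)
  expect_equal(atrophy_rate(0.7, mat, "CSF"), 0)
  # bounded between G_h and G_h + G_c for every admissible concentration
  r <- atrophy_rate(seq(0, 1, by = 0.01), mat, "WM")
  expect_true(all(r >= 0.0015 - 1e-12 & r <= 0.005 + 1e-12))
})

test_that("atrophy factor update: decay steps, 40-year limits, floor clamp", {
  mat <- default_materials()
  expect_equal(update_atrophy_factor(1, 0, 1, mat, "WM"), 0.9985, tolerance = 1e-9)
  # saturated concentration for 40 years reaches the accelerated limit
  th <- 1
  for (k in 1:400) th <- update_atrophy_factor(th, 1, 0.1, mat, "WM")
  expect_equal(th, 1 - 0.005 * 40, tolerance = 1e-8)
  expect_equal(update_atrophy_factor(1, 0.9, 1, mat, "VENT"), 1)
  expect_warning(update_atrophy_factor(0.5005, 1, 1, mat, "WM"), "floor")
  expect_error(update_atrophy_factor(1.2, 0, 1, mat, "WM"), "theta_n")
  # monotone non-increasing under any concentration history
  set.seed(3)
  th <- 1
  for (k in 1:50) {
    th_new <- update_atrophy_factor(th, runif(1), 0.25, mat, "GM")
    expect_lte(th_new, th)
    th <- th_new
  }
})

test_that("multiplicative split: identities, compatible shrinkage, volume ratios", {
  F2 <- random_F(2)
  s1 <- deformation_split(F2, 1)
  expect_equal(s1$F_e, F2)
  expect_equal(s1$F_a, diag(2))
  s <- deformation_split(diag(sqrt(0.8), 2), 0.8)
  expect_equal(s$F_e, diag(2), tolerance = 1e-12)
  expect_equal(s$J_a, 0.8)
  F3 <- random_F(3)
  F3 <- F3 / det(F3)^(1 / 3)  # J = 1
  s3 <- deformation_split(F3, 0.8)
  expect_equal(s3$J_e, 1.25, tolerance = 1e-10)
  expect_equal(det(s3$F_a), 0.8, tolerance = 1e-12)
  expect_equal(s3$F_e %*% s3$F_a, F3, tolerance = 1e-12)
  expect_error(deformation_split(diag(c(-1, 1)), 1), "inversion")
})

test_that("strain energy: reference state, compression blow-up, small-strain moduli", {
  expect_equal(strain_energy(diag(2), 1, 2, 64.67), 0)
  expect_equal(strain_energy(diag(3), 0.9, 1, 32.33), 0)
  # energy diverges as J_e -> 0+
  en <- vapply(c(0.5, 0.1, 0.02), function(s) strain_energy(diag(s, 2), 1, 2, 64.67),
               numeric(1))
  expect_true(all(diff(en) > 0))
  expect_gt(en[3], 1e2)
  # uniaxial-stretch curvature matches the linear-elastic modulus lambda + 2 mu
  mu <- 1.3; la <- 20
  h <- 1e-4
  psi <- function(e) strain_energy(diag(c(1 + e, 1, 1)), 1, mu, la)
  curv <- (psi(h) - 2 * psi(0) + psi(-h)) / h^2
  expect_equal(curv, la + 2 * mu, tolerance = 1e-4)
})

test_that("Piola stress is the exact work conjugate of the stored energy", {
  set.seed(101)
  worst <- 0
  for (rep in 1:100) for (d in 2:3) {
    F <- random_F(d)
    th <- runif(1, 0.6, 1); mu <- runif(1, 0.5, 3); la <- runif(1, 5, 70)
    P <- atrophysim:::piola_stress_total(F, th, mu, la)
    h <- 1e-6
    Pfd <- matrix(0, d, d)
    for (i in 1:d) for (J in 1:d) {
      Fp <- F; Fp[i, J] <- Fp[i, J] + h
      Fm <- F; Fm[i, J] <- Fm[i, J] - h
      Pfd[i, J] <- (atrophysim:::strain_energy_total(Fp, th, mu, la) -
                      atrophysim:::strain_energy_total(Fm, th, mu, la)) / (2 * h)
    }
    worst <- max(worst, max(abs(P - Pfd)) / max(abs(P)))
  }
  expect_lt(worst, 1e-6)
})

test_that("stress-free states: elastic identity and pure rotations", {
  for (d in 2:3) {
    expect_equal(max(abs(piola_stress(diag(d), 0.85, 2, 30))), 0)
    R <- random_rotation(d)
    expect_equal(max(abs(piola_stress(R, 0.85, 2, 30))), 0, tolerance = 1e-12)
    # objectivity of the stored energy
    F_e <- random_F(d)
    Q <- random_rotation(d)
    expect_equal(strain_energy(Q %*% F_e, 0.9, 2, 30),
                 strain_energy(F_e, 0.9, 2, 30), tolerance = 1e-12)
  }
})

test_that("Cauchy stress and Jaumann tangent: limits, symmetry, finite differences", {
  # linear-elastic limit at the reference state
  mu <- 2; la <- 64.67
  st <- cauchy_stress_and_tangent(diag(2), 1, mu, la)
  expect_equal(max(abs(st$sigma)), 0)
  Ciso <- array(0, c(2, 2, 2, 2))
  for (i in 1:2) for (j in 1:2) for (k in 1:2) for (l in 1:2)
    Ciso[i, j, k, l] <- la * (i == j) * (k == l) +
      mu * ((i == k) * (j == l) + (i == l) * (j == k))
  expect_equal(st$tangent, Ciso, tolerance = 1e-12)
  # compatible shrinkage is stress-free
  st2 <- cauchy_stress_and_tangent(diag(0.8^(1 / 3), 3), 0.8, 1, 32.33)
  expect_equal(max(abs(st2$sigma)), 0, tolerance = 1e-12)
  # random states: symmetric sigma, FD check of the Jaumann modulus
  set.seed(202)
  worst <- 0
  for (rep in 1:40) for (d in 2:3) {
    F <- random_F(d, 0.1)
    th <- runif(1, 0.7, 1)
    st <- cauchy_stress_and_tangent(F, th, mu, la)
    expect_equal(st$sigma, t(st$sigma), tolerance = 1e-12)
    J <- det(F)
    tau_of <- function(Fx) atrophysim:::piola_stress_total(Fx, th, mu, la) %*% t(Fx)
    h <- 1e-6
    for (k in 1:d) for (l in k:d) {
      D <- matrix(0, d, d); D[k, l] <- D[k, l] + 0.5; D[l, k] <- D[l, k] + 0.5
      dtau <- (tau_of((diag(d) + h * D) %*% F) -
                 tau_of((diag(d) - h * D) %*% F)) / (2 * h)
      CD <- matrix(0, d, d)
      for (i in 1:d) for (j in 1:d) CD[i, j] <- sum(st$tangent[i, j, , ] * D)
      worst <- max(worst, max(abs(dtau - J * CD)) / (J * max(abs(st$tangent))))
    }
  }
  expect_lt(worst, 1e-4)
})
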