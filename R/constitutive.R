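# Atrophy-coupled hyperelastic material law.
#
# Kinematics: multiplicative split F = F_e F_a with isotropic atrophy part
# F_a = theta^(1/dim) I, so det(F_a) = theta is the fraction of local
# measure retained (volume in 3D, in-plane area in the plane-strain 2D
# convention). Energy: atrophy-weighted compressible neo-Hookean
#   Psi0(F) = theta * [ mu/2 (Fe:Fe - dim - 2 ln Je) + lambda/2 ln^2 Je ].
# The first Piola-Kirchhoff stress is the exact derivative dPsi0/dF, which
# carries a theta^(1-1/dim) prefactor on the intermediate-configuration
# stress via the chain rule through F_e = theta^(-1/dim) F; work conjugacy
# is enforced by a finite-difference test.

#' Logistic growth rate from protein kinetics
#'
#' Reparameterizes the two-species kinetics (production `k0`, clearances
#' `k1`, `k1_tilde`, conversion `k12`) into the single Fisher-Kolmogorov
#' growth rate `alpha = k12*k0/k1 - k1_tilde`. May be negative; the caller
#' decides whether that is admissible.
#'
#' @param k0 healthy-protein production rate (1/year).
#' @param k1 healthy-protein clearance rate (1/year), must be > 0.
#' @param k1_tilde misfolded-protein clearance rate (1/year).
#' @param k12 conversion rate (1/year).
#' @return Growth rate alpha (1/year).
#' @export
kinetic_alpha <- function(k0, k1, k1_tilde, k12) {
  if (any(k1 <= 0)) stop_atrophy("kinetic_alpha: healthy clearance rate k1 must be > 0")
  k12 * k0 / k1 - k1_tilde
}

#' Smooth Heaviside activation
#'
#' Logistic approximation of the step that switches atrophy from the
#' healthy to the accelerated rate: `1 / (1 + exp(-beta * (c - c_crit)))`.
#' Increases with `c`, equals 0.5 at `c = c_crit`; `beta` sets the
#' transition sharpness (transition width ~ 5/beta in concentration units).
#'
#' @param c biomarker concentration (dimensionless).
#' @param c_crit critical concentration.
#' @param beta transition sharpness (> 0), default 50.
#' @return Activation in (0, 1).
#' @export
smooth_heaviside <- function(c, c_crit, beta = 50) {
  stopifnot(beta > 0)
  1 / (1 + exp(-beta * (c - c_crit)))
}

#' Atrophy (volume-loss) rate
#'
#' Magnitude of d(theta)/dt: `G_h + G_c * H(c - c_crit)`, applied as decay
#' of the atrophy factor. Limits: `G_h` for `c << c_crit`,
#' `G_h + G_c` for `c >> c_crit`. Regions without atrophy parameters
#' (ventricles, CSF) return 0.
#'
#' @param c biomarker concentration (vector ok).
#' @param mat a [material_table].
#' @param region region label (scalar) or vector matching `c`.
#' @param beta smooth-Heaviside sharpness.
#' @return Loss rate in 1/year (>= 0).
#' @export
atrophy_rate <- function(c, mat, region = "WM", beta = 50) {
  ri <- match(region, region_labels())
  if (anyNA(ri)) stop_atrophy("unknown region: %s", paste(region[is.na(ri)], collapse = ", "))
  G_h <- mat$G_h[ri]; G_c <- mat$G_c[ri]; cc <- mat$c_crit[ri]
  out <- ifelse(is.na(G_h), 0,
                G_h + ifelse(is.na(G_c), 0, G_c * smooth_heaviside(c, cc, beta)))
  unname(out)
}

#' One finite-difference update of the atrophy factor
#'
#' Explicit decay step `theta = theta_n - [G_h + G_c H(c - c_crit)] dt`,
#' floored at `floor` (default 0.5) to keep `det F_a` bounded away from
#' zero; hitting the floor raises a warning and clamps.
#'
#' @param theta_n converged atrophy factor at the previous step, in (0, 1].
#' @param c biomarker concentration at the quadrature point.
#' @param dt time increment (years, > 0).
#' @param mat a [material_table].
#' @param region region label (scalar or vector).
#' @param beta smooth-Heaviside sharpness.
#' @param floor minimum admissible theta.
#' @return Updated theta (same length as `theta_n`).
#' @export
update_atrophy_factor <- function(theta_n, c, dt, mat, region = "WM",
                                  beta = 50, floor = 0.5) {
  stopifnot(dt > 0)
  if (any(theta_n <= 0 | theta_n > 1))
    stop_atrophy("theta_n must lie in (0, 1]")
  th <- theta_n - atrophy_rate(c, mat, region, beta) * dt
  if (any(th < floor)) {
    warning(sprintf("atrophy factor clamped at floor %.3g for %d point(s)",
                    floor, sum(th < floor)))
    th <- pmax(th, floor)
  }
  th
}

#' Multiplicative split of the deformation gradient
#'
#' `F_a = theta^(1/dim) I`, `F_e = F theta^(-1/dim)`; `det F_a = theta`
#' exactly and `J_e = J / theta`.
#'
#' @param F deformation gradient (dim x dim matrix, det > 0).
#' @param theta atrophy factor (> 0).
#' @return List with `F_a`, `F_e`, `J`, `J_a = theta`, `J_e`.
#' @export
deformation_split <- function(F, theta) {
  d <- nrow(F)
  J <- det(F)
  if (J <= 0) stop_atrophy("deformation_split: det F = %.3g <= 0 (element inversion)", J)
  if (theta <= 0) stop_atrophy("deformation_split: theta must be > 0")
  s <- theta^(1 / d)
  list(F_a = diag(s, d), F_e = F / s, J = J, J_a = theta, J_e = J / theta)
}

#' Atrophy-weighted neo-Hookean strain energy density
#'
#' `Psi0 = theta * [ mu/2 (Fe:Fe - dim - 2 ln Je) + lambda/2 ln^2 Je ]`,
#' zero at `F_e = I`, divergent as `J_e -> 0+`.
#'
#' @param F_e elastic part of the deformation gradient (det > 0).
#' @param theta atrophy factor.
#' @param mu,lambda Lame constants (kPa).
#' @return Energy density (kPa = kJ/m^3).
#' @export
strain_energy <- function(F_e, theta, mu, lambda) {
  d <- nrow(F_e)
  Je <- det(F_e)
  if (Je <= 0) stop_atrophy("strain_energy: det F_e <= 0")
  theta * (0.5 * mu * (sum(F_e * F_e) - d - 2 * log(Je)) + 0.5 * lambda * log(Je)^2)
}

# energy as a function of the total deformation gradient (test oracle path)
strain_energy_total <- function(F, theta, mu, lambda) {
  d <- nrow(F)
  strain_energy(F / theta^(1 / d), theta, mu, lambda)
}

#' First Piola-Kirchhoff stress
#'
#' Exact work conjugate of the atrophy-weighted energy with respect to the
#' total deformation gradient:
#' `P = theta^(1-1/dim) [ mu F_e + (lambda ln Je - mu) F_e^{-T} ]`.
#' Vanishes for `F_e = I` (stress-free shrunken state) and for pure
#' rotations of the elastic part.
#'
#' @param F_e elastic part of the deformation gradient (det > 0).
#' @param theta atrophy factor.
#' @param mu,lambda Lame constants (kPa).
#' @return P (dim x dim, kPa).
#' @export
piola_stress <- function(F_e, theta, mu, lambda) {
  d <- nrow(F_e)
  Je <- det(F_e)
  if (Je <= 0) stop_atrophy("piola_stress: det F_e <= 0 (singular or inverted state)")
  FinvT <- t(solve(F_e))
  theta^(1 - 1 / d) * (mu * F_e + (lambda * log(Je) - mu) * FinvT)
}

# P as a function of total F; used by the assembly and tangent
piola_stress_total <- function(F, theta, mu, lambda) {
  d <- nrow(F)
  piola_stress(F / theta^(1 / d), theta, mu, lambda)
}

# dP/dF as a dim^2 x dim^2 matrix in (i,J) x (k,L) ordering with i fastest
piola_tangent_total <- function(F, theta, mu, lambda) {
  d <- nrow(F)
  J <- det(F)
  if (J <= 0) stop_atrophy("piola_tangent: det F <= 0")
  Fi <- solve(F)         # Fi[J,i] = F^{-1}
  FiT <- t(Fi)
  mu_eff <- mu * theta^(1 - 2 / d)
  s <- theta * (lambda * log(J / theta) - mu)
  A <- array(0, c(d, d, d, d))
  for (i in 1:d) for (J_ in 1:d) for (k in 1:d) for (L in 1:d)
    A[i, J_, k, L] <- mu_eff * (i == k) * (J_ == L) +
      theta * lambda * FiT[i, J_] * FiT[k, L] -
      s * FiT[i, L] * FiT[k, J_]
  A
}

#' Cauchy stress and Jaumann-rate consistent tangent
#'
#' Returns the (symmetric) Cauchy stress `sigma = J^{-1} P F^T` and the
#' spatial tangent in the Jaumann-rate convention used by corotational FE
#' updates: for a symmetric velocity-gradient perturbation D,
#' `delta(J sigma) = J C : D`. Built from the exact material tangent dP/dF
#' pushed forward to the current configuration plus the stress-geometric
#' terms, then minor-symmetrized.
#'
#' @param F total deformation gradient (det > 0).
#' @param theta atrophy factor.
#' @param mu,lambda Lame constants (kPa).
#' @return List with `sigma` (dim x dim) and `tangent`
#'   (dim x dim x dim x dim array, minor symmetries in (i,j) and (k,l)).
#' @export
cauchy_stress_and_tangent <- function(F, theta, mu, lambda) {
  d <- nrow(F)
  J <- det(F)
  if (J <= 0) stop_atrophy("cauchy_stress_and_tangent: det F <= 0")
  P <- piola_stress_total(F, theta, mu, lambda)
  tau <- P %*% t(F)                    # Kirchhoff stress
  sigma <- tau / J
  if (any(!is.finite(sigma))) stop_atrophy("non-finite stress entries")
  A <- piola_tangent_total(F, theta, mu, lambda)
  # b_ijkl = F_jJ F_lL A_iJkL  (delta tau = b : L + tau L^T-term)
  b <- array(0, c(d, d, d, d))
  for (i in 1:d) for (j in 1:d) for (k in 1:d) for (l in 1:d)
    b[i, j, k, l] <- sum(F[j, ] * (A[i, , k, ] %*% F[l, ]))
  Cj <- array(0, c(d, d, d, d))
  for (i in 1:d) for (j in 1:d) for (k in 1:d) for (l in 1:d)
    Cj[i, j, k, l] <- b[i, j, k, l] + (j == k) * tau[i, l]
  # minor-symmetrize in (k,l) then (i,j)
  Cj <- (Cj + aperm(Cj, c(1, 2, 4, 3))) / 2
  Cj <- (Cj + aperm(Cj, c(2, 1, 3, 4))) / 2
  list(sigma = sigma, tangent = Cj / J)
}
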