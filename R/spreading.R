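# Fisher-Kolmogorov biomarker spreading on the labeled mesh:
#   dc/dt = d Laplacian(c) + alpha c (1 - c)
# with region-wise diffusivity d (zero in ventricles/CSF: no diffusive
# exchange there) and logistic growth alpha, natural (zero-flux) boundary
# conditions on the exterior, backward-Euler time stepping with Newton on
# the reaction term, lumped mass, and a [0,1] safety clip.

#' Spreading parameters
#'
#' Region-wise diffusivity and growth rate (taken from a
#' [material_table]) plus the seeding protocol: an initial concentration
#' `c0_seed` in the elements of `seed_region`.
#'
#' @param mat a [material_table].
#' @param c0_seed initial seeded concentration (default 0.3).
#' @param seed_region region label carrying the seed (default `"HIPPO"`).
#' @return List of class `spreading_params`.
#' @export
spreading_params <- function(mat = default_materials(), c0_seed = 0.3,
                             seed_region = "HIPPO") {
  stopifnot(c0_seed >= 0, c0_seed <= 1)
  structure(list(d = setNames(mat$d, rownames(mat)),
                 alpha = setNames(mat$alpha, rownames(mat)),
                 c0_seed = c0_seed, seed_region = seed_region),
            class = "spreading_params")
}

#' Concentration field
#'
#' Nodal misfolded-protein concentration, dimensionless in `[0, 1]`, with a
#' time stamp in years.
#'
#' @param values numeric vector, one entry per mesh node.
#' @param time time stamp (years).
#' @return Object of class `concentration_field`.
#' @export
concentration_field <- function(values, time = 0) {
  if (any(values < -1e-12 | values > 1 + 1e-12))
    stop_atrophy("concentration values must lie in [0, 1]")
  structure(list(values = pmin(1, pmax(0, values)), time = time),
            class = "concentration_field")
}

#' Seed the biomarker in a region
#'
#' Sets `c = c0_seed` at every node incident to an element of the seed
#' region (nodes shared with neighboring regions take the seed value), and
#' 0 elsewhere.
#'
#' @param mesh a [labeled_mesh].
#' @param params a [spreading_params].
#' @return A [concentration_field] at time 0.
#' @export
seed_concentration <- function(mesh, params) {
  r <- match(params$seed_region, mesh$region_names)
  if (is.na(r) || !any(mesh$region == r))
    stop_atrophy("seed region '%s' not present in mesh", params$seed_region)
  v <- numeric(nrow(mesh$nodes))
  seed_nodes <- unique(as.vector(mesh$elements[mesh$region == r, ]))
  v[seed_nodes] <- params$c0_seed
  concentration_field(v, 0)
}

#' Closed-form logistic solution (spatially uniform oracle)
#'
#' Solution of `dc/dt = alpha c (1 - c)`:
#' `c(t) = c0 e^{alpha t} / (1 - c0 + c0 e^{alpha t})`.
#'
#' @param c0 initial value in `[0, 1]`.
#' @param alpha growth rate (1/year).
#' @param t time (years).
#' @return Concentration at time `t`.
#' @export
closed_form_logistic <- function(c0, alpha, t) {
  stopifnot(c0 >= 0, c0 <= 1)
  # algebraically equal to c0 e^{at} / (1 - c0 + c0 e^{at}), but stable
  # for large alpha * t
  c0 / (c0 + (1 - c0) * exp(-alpha * t))
}

#' Logistic reaction term and its derivative
#'
#' `f = alpha c (1 - c)` and `df/dc = alpha (1 - 2c)`, the pair needed by
#' an implicit (Newton) treatment of the source term.
#'
#' @param c concentration (vector ok).
#' @param alpha growth rate.
#' @return List with `f` and `df_dc`.
#' @export
reaction_term <- function(c, alpha) {
  list(f = alpha * c * (1 - c), df_dc = alpha * (1 - 2 * c))
}

# Precomputed operator for repeated stepping: stiffness with region-wise d,
# lumped mass, and mass-weighted nodal alpha.
fk_operator <- function(mesh, params) {
  fem <- fem_gradients(mesh)
  d_e <- params$d[mesh$region_names[mesh$region]]
  a_e <- params$alpha[mesh$region_names[mesh$region]]
  K <- assemble_diffusion(mesh, fem, d_e)
  M <- lumped_mass(mesh, fem)
  Ma <- lumped_mass(mesh, fem, a_e)
  list(K = K, M = M, alpha_node = Ma / M, n = nrow(mesh$nodes))
}

#' Advance the concentration one implicit time step
#'
#' Backward-Euler step of the Fisher-Kolmogorov equation with Newton
#' iteration on the logistic source; zero-flux boundaries are natural in
#' the weak form. After the solve, values are clipped to `[0, 1]`; if the
#' total clipped mass exceeds 1e-6 a message reports it.
#'
#' @param field a [concentration_field].
#' @param mesh a [labeled_mesh].
#' @param params a [spreading_params].
#' @param dt time step (years, > 0).
#' @param op optional precomputed operator (from repeated stepping);
#'   recomputed when NULL.
#' @param tol Newton tolerance on the scaled residual.
#' @param max_iter Newton iteration cap.
#' @return Updated [concentration_field] at `field$time + dt`.
#' @export
step_concentration <- function(field, mesh, params, dt, op = NULL,
                               tol = 1e-12, max_iter = 30) {
  stopifnot(dt > 0)
  if (is.null(op)) op <- fk_operator(mesh, params)
  c0 <- field$values
  a <- op$alpha_node
  M <- op$M
  x <- c0
  scale <- max(M)
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    R <- M * (x - c0) + dt * as.vector(op$K %*% x) - dt * M * a * x * (1 - x)
    if (max(abs(R)) / scale < tol) { conv <- TRUE; break }
    Jm <- Matrix::Diagonal(op$n, M - dt * M * a * (1 - 2 * x)) + dt * op$K
    x <- x - as.vector(Matrix::solve(Jm, R))
  }
  if (!conv) {
    R <- M * (x - c0) + dt * as.vector(op$K %*% x) - dt * M * a * x * (1 - x)
    if (max(abs(R)) / scale >= tol * 100)
      stop_atrophy("concentration step failed to converge: scaled residual %.3g after %d iterations",
                   max(abs(R)) / scale, max_iter)
  }
  clip <- sum(pmax(x - 1, 0) + pmax(-x, 0))
  if (clip > 1e-6)
    message(sprintf("concentration clipped to [0,1]; total clipped mass %.3g", clip))
  concentration_field(pmin(1, pmax(0, x)), field$time + dt)
}
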