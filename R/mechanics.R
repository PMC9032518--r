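# Quasistatic nonlinear finite-element equilibrium (total-Lagrangian P1
# simplices, single-point quadrature) and the staggered coupling driver:
# per time increment, (AD mode) advance the biomarker, update the atrophy
# factor at quadrature points, then re-solve mechanical equilibrium with
# zero body force and zero displacement on the anchoring boundary set.

# Per-element kinematics: deformation gradient components from nodal
# displacements. Returns list of d x d component vectors F[[i]][[J]].
elem_def_grad <- function(mesh, fem, u) {
  el <- mesh$elements
  d <- mesh$dim
  d1 <- d + 1L
  F <- vector("list", d)
  for (i in seq_len(d)) {
    F[[i]] <- vector("list", d)
    for (J in seq_len(d)) {
      f <- if (i == J) rep(1, nrow(el)) else rep(0, nrow(el))
      for (a in seq_len(d1)) f <- f + u[el[, a], i] * fem$G[, a, J]
      F[[i]][[J]] <- f
    }
  }
  F
}

elem_detF <- function(F, d) {
  if (d == 2L) F[[1]][[1]] * F[[2]][[2]] - F[[1]][[2]] * F[[2]][[1]]
  else F[[1]][[1]] * (F[[2]][[2]] * F[[3]][[3]] - F[[2]][[3]] * F[[3]][[2]]) -
    F[[1]][[2]] * (F[[2]][[1]] * F[[3]][[3]] - F[[2]][[3]] * F[[3]][[1]]) +
    F[[1]][[3]] * (F[[2]][[1]] * F[[3]][[2]] - F[[2]][[2]] * F[[3]][[1]])
}

# inverse components Finv[[J]][[i]] = (F^-1)_{Ji}
elem_invF <- function(F, J, d) {
  Fi <- vector("list", d)
  for (k in seq_len(d)) Fi[[k]] <- vector("list", d)
  if (d == 2L) {
    Fi[[1]][[1]] <- F[[2]][[2]] / J;  Fi[[1]][[2]] <- -F[[1]][[2]] / J
    Fi[[2]][[1]] <- -F[[2]][[1]] / J; Fi[[2]][[2]] <- F[[1]][[1]] / J
  } else {
    cof <- function(i1, i2, j1, j2) F[[i1]][[j1]] * F[[i2]][[j2]] - F[[i1]][[j2]] * F[[i2]][[j1]]
    Fi[[1]][[1]] <- cof(2, 3, 2, 3) / J; Fi[[1]][[2]] <- -cof(1, 3, 2, 3) / J; Fi[[1]][[3]] <- cof(1, 2, 2, 3) / J
    Fi[[2]][[1]] <- -cof(2, 3, 1, 3) / J; Fi[[2]][[2]] <- cof(1, 3, 1, 3) / J; Fi[[2]][[3]] <- -cof(1, 2, 1, 3) / J
    Fi[[3]][[1]] <- cof(2, 3, 1, 2) / J; Fi[[3]][[2]] <- -cof(1, 3, 1, 2) / J; Fi[[3]][[3]] <- cof(1, 2, 1, 2) / J
  }
  Fi
}

# assemble residual vector and (optionally) tangent triplets for the
# morphoelastic neo-Hookean problem; theta, mu, lambda are per element
assemble_mechanics <- function(mesh, fem, u, theta, mu, lambda, tangent = TRUE) {
  el <- mesh$elements
  d <- mesh$dim
  d1 <- d + 1L
  ne <- nrow(el)
  n <- nrow(mesh$nodes)
  F <- elem_def_grad(mesh, fem, u)
  J <- elem_detF(F, d)
  if (any(J <= 0))
    stop_atrophy("element inversion: det F <= 0 in %d element(s) (first: %d)",
                 sum(J <= 0), which(J <= 0)[1])
  Fi <- elem_invF(F, J, d)           # Fi[[J]][[i]] = (F^-1)_{Ji} = F^{-T}_{iJ}
  mu_eff <- mu * theta^(1 - 2 / d)
  s <- theta * (lambda * log(J / theta) - mu)
  V <- fem$V
  # P_iJ = mu_eff F_iJ + s * F^{-T}_{iJ}
  P <- vector("list", d)
  for (i in seq_len(d)) {
    P[[i]] <- vector("list", d)
    for (Jx in seq_len(d)) P[[i]][[Jx]] <- mu_eff * F[[i]][[Jx]] + s * Fi[[Jx]][[i]]
  }
  # residual R[(node-1)*d + i] = sum_e V P_iJ G_aJ
  Rv <- numeric(n * d)
  for (a in seq_len(d1)) for (i in seq_len(d)) {
    acc <- 0
    for (Jx in seq_len(d)) acc <- acc + P[[i]][[Jx]] * fem$G[, a, Jx]
    contrib <- rowsum(V * acc, el[, a])
    idx <- (as.integer(rownames(contrib)) - 1L) * d + i
    Rv[idx] <- Rv[idx] + contrib[, 1]
  }
  if (!tangent) return(list(R = Rv, J = J))
  # w[[a]][[i]] = sum_J G_aJ F^{-T}_{iJ}
  w <- vector("list", d1)
  for (a in seq_len(d1)) {
    w[[a]] <- vector("list", d)
    for (i in seq_len(d)) {
      acc <- 0
      for (Jx in seq_len(d)) acc <- acc + fem$G[, a, Jx] * Fi[[Jx]][[i]]
      w[[a]][[i]] <- acc
    }
  }
  gg <- vector("list", d1 * d1)   # GG_ab
  for (a in seq_len(d1)) for (b in seq_len(d1)) {
    acc <- 0
    for (Jx in seq_len(d)) acc <- acc + fem$G[, a, Jx] * fem$G[, b, Jx]
    gg[[(a - 1L) * d1 + b]] <- acc
  }
  nblk <- d1 * d1 * d * d
  ti <- vector("list", nblk); tj <- vector("list", nblk); tx <- vector("list", nblk)
  blk <- 0L
  tl <- theta * lambda
  for (a in seq_len(d1)) for (b in seq_len(d1)) {
    GGab <- gg[[(a - 1L) * d1 + b]]
    for (i in seq_len(d)) for (k in seq_len(d)) {
      blk <- blk + 1L
      val <- tl * w[[a]][[i]] * w[[b]][[k]] - s * w[[a]][[k]] * w[[b]][[i]]
      if (i == k) val <- val + mu_eff * GGab
      ti[[blk]] <- (el[, a] - 1L) * d + i
      tj[[blk]] <- (el[, b] - 1L) * d + k
      tx[[blk]] <- V * val
    }
  }
  K <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(n * d, n * d))
  list(R = Rv, K = K, J = J)
}

#' Solve quasistatic mechanical equilibrium
#'
#' Newton iteration on the weak form of the balance of linear momentum with
#' zero body force: `Div(P) = 0` with `u = 0` on the Dirichlet node set
#' and the atrophy field entering through the multiplicative split.
#'
#' @param mesh a [labeled_mesh].
#' @param theta per-element atrophy factor (quadrature-point state).
#' @param mat a [material_table].
#' @param u_init optional initial displacement guess (nodes x dim), zeros
#'   when NULL.
#' @param dirichlet name of a boundary node set (default `"csf_outer"`),
#'   an integer vector of node indices, or NULL for none.
#' @param pin_dofs optional integer vector of global dof indices
#'   (`(node-1)*dim + component`) to fix in addition to `dirichlet`
#'   (e.g. to pin rigid modes of a free body).
#' @param tol Newton tolerance on the residual infinity norm (kPa mm^dim-1).
#' @param max_iter Newton iteration cap.
#' @param fem optional precomputed gradients (from [fem_gradients]).
#' @return List with `u` (nodes x dim, mm), `iterations`, `residual`,
#'   `trace` (residual norms per iteration).
#' @export
solve_equilibrium <- function(mesh, theta, mat, u_init = NULL,
                              dirichlet = "csf_outer", pin_dofs = NULL,
                              tol = 1e-8, max_iter = 50, fem = NULL) {
  d <- mesh$dim
  n <- nrow(mesh$nodes)
  if (is.null(fem)) fem <- fem_gradients(mesh)
  mu_e <- mat$mu[mesh$region]
  la_e <- mat$lambda[mesh$region]
  theta <- rep(theta, length.out = nrow(mesh$elements))
  fixed <- integer(0)
  if (!is.null(dirichlet)) {
    bn <- if (is.character(dirichlet)) {
      if (is.null(mesh$boundary_sets[[dirichlet]]))
        stop_atrophy("boundary set '%s' not found", dirichlet)
      mesh$boundary_sets[[dirichlet]]
    } else as.integer(dirichlet)
    if (!length(bn)) stop_atrophy("Dirichlet node set is empty")
    fixed <- as.vector(outer(seq_len(d), (bn - 1L) * d, "+"))
  }
  fixed <- sort(unique(c(fixed, pin_dofs)))
  free <- setdiff(seq_len(n * d), fixed)
  u <- u_init %||% matrix(0, n, d)
  uv <- as.vector(t(u))  # dof order: node-major, component fastest
  uv[fixed] <- 0
  umat <- function(v) matrix(v, n, d, byrow = TRUE)
  trace <- numeric(0)
  res <- Inf
  for (it in 0:max_iter) {
    asm <- assemble_mechanics(mesh, fem, umat(uv), theta, mu_e, la_e, tangent = TRUE)
    res <- if (length(free)) max(abs(asm$R[free])) else 0
    trace <- c(trace, res)
    if (!is.finite(res))
      stop_atrophy("Newton diverged (non-finite residual) at iteration %d; trace: %s",
                   it, paste(sprintf("%.3g", trace), collapse = " "))
    if (res < tol) {
      return(list(u = umat(uv), iterations = it, residual = res, trace = trace))
    }
    if (it == max_iter) break
    du <- as.vector(Matrix::solve(asm$K[free, free, drop = FALSE], -asm$R[free]))
    # backtracking line search on the residual norm
    step <- 1
    for (ls in 1:8) {
      uv_try <- uv
      uv_try[free] <- uv[free] + step * du
      ok <- TRUE
      rtry <- Inf
      tryCatch({
        a2 <- assemble_mechanics(mesh, fem, umat(uv_try), theta, mu_e, la_e, tangent = FALSE)
        rtry <- max(abs(a2$R[free]))
      }, error = function(e) ok <<- FALSE)
      if (ok && is.finite(rtry) && (rtry < res || step < 0.2)) break
      step <- step / 2
    }
    uv[free] <- uv[free] + step * du
  }
  stop_atrophy("Newton failed to converge: residual %.3g after %d iterations (trace: %s); consider substepping the atrophy increment",
               res, max_iter, paste(sprintf("%.3g", utils::tail(trace, 6)), collapse = " "))
}

#' Simulation configuration
#'
#' @param t_end simulated age span (years), default 40.
#' @param dt time increment (years), default 0.1.
#' @param mode `"healthy"` (constant tissue atrophy rates, no biomarker)
#'   or `"ad"` (biomarker-coupled accelerated atrophy).
#' @param newton_tol residual infinity-norm tolerance for equilibrium.
#' @param newton_max_iter Newton iteration cap.
#' @param dirichlet boundary set fixed in space (default `"csf_outer"`).
#' @param output_every store displacement/concentration snapshots every
#'   this many steps.
#' @param beta smooth-Heaviside sharpness of the atrophy activation.
#' @param theta_floor minimum admissible atrophy factor.
#' @param seed RNG seed recorded with the run (the solver is deterministic).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(t_end = 40, dt = 0.1, mode = c("ad", "healthy"),
                              newton_tol = 1e-8, newton_max_iter = 50,
                              dirichlet = "csf_outer", output_every = 40,
                              beta = 50, theta_floor = 0.5, seed = 1L) {
  mode <- match.arg(mode)
  if (dt <= 0 || (t_end > 0 && dt > t_end)) stop_atrophy("need 0 < dt <= t_end")
  if (newton_tol <= 0) stop_atrophy("newton_tol must be > 0")
  structure(list(t_end = t_end, dt = dt, mode = mode, newton_tol = newton_tol,
                 newton_max_iter = newton_max_iter, dirichlet = dirichlet,
                 output_every = as.integer(output_every), beta = beta,
                 theta_floor = theta_floor, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Run the staggered atrophy simulation
#'
#' Per time increment: (AD mode only) advance the biomarker concentration
#' by one implicit step; update the per-element atrophy factor (healthy
#' mode uses the constant rate `G_h`, AD mode the concentration-gated rate
#' `G_h + G_c H(c - c_crit)` with c interpolated at the element
#' quadrature point); then re-solve mechanical equilibrium. The coupling is
#' one-way: deformation does not feed back into diffusion, which is solved
#' on the reference configuration. If a Newton solve fails, the atrophy
#' increment is bisected and reapplied (up to 4 levels).
#'
#' @param mesh a [labeled_mesh].
#' @param mat a [material_table].
#' @param config a [simulation_config].
#' @param spreading a [spreading_params] (AD mode); defaults to Table-style
#'   parameters from `mat`.
#' @param quiet suppress progress messages.
#' @return Object of class `simulation_result`: time series of region
#'   volumes (deformed), sulcal pocket volumes, extrema/means of theta and
#'   c, displacement/concentration snapshots, final fields, and a
#'   convergence log.
#' @export
run_simulation <- function(mesh, mat = default_materials(),
                           config = simulation_config(),
                           spreading = spreading_params(mat),
                           quiet = TRUE) {
  d <- mesh$dim
  ne <- nrow(mesh$elements)
  fem <- fem_gradients(mesh)
  nsteps <- if (config$t_end == 0) 0L else round(config$t_end / config$dt)
  rn <- mesh$region_names
  reg <- mesh$region
  G_h <- mat$G_h[reg]; G_c <- mat$G_c[reg]; c_crit <- mat$c_crit[reg]
  tissue <- !is.na(G_h)
  theta <- rep(1, ne)
  u <- matrix(0, nrow(mesh$nodes), d)
  ad <- config$mode == "ad"
  cf <- NULL; op <- NULL
  if (ad) {
    cf <- seed_concentration(mesh, spreading)
    op <- fk_operator(mesh, spreading)
  }
  times <- numeric(nsteps + 1L)
  vols <- matrix(NA_real_, nsteps + 1L, 5, dimnames = list(NULL, rn))
  min_theta <- numeric(nsteps + 1L)
  mean_c <- max_c <- numeric(nsteps + 1L)
  sul <- matrix(NA_real_, nsteps + 1L, length(mesh$sulci),
                dimnames = list(NULL, names(mesh$sulci)))
  snapshots <- list()
  convlog <- list()
  clamped <- 0L
  record <- function(k) {
    vols[k, ] <<- region_measures(mesh, mesh$nodes + u)[rn]
    min_theta[k] <<- min(theta)
    mean_c[k] <<- if (ad) mean(cf$values) else 0
    max_c[k] <<- if (ad) max(cf$values) else 0
    if (length(mesh$sulci)) {
      v <- element_measures(mesh, mesh$nodes + u)
      sul[k, ] <<- vapply(mesh$sulci, function(ix) sum(v[ix]), numeric(1))
    }
  }
  snap <- function(t) {
    snapshots[[length(snapshots) + 1L]] <<- list(
      time = t, u = u, c = if (ad) cf$values else NULL, theta = theta)
  }
  record(1L); times[1] <- 0; snap(0)
  if (nsteps > 0) for (k in seq_len(nsteps)) {
    t <- k * config$dt
    if (ad) {
      cf <- step_concentration(cf, mesh, spreading, config$dt, op = op)
      c_e <- rowMeans(matrix(cf$values[mesh$elements[, seq_len(d + 1L)]], ncol = d + 1L))
    }
    rate <- numeric(ne)
    rate[tissue] <- if (ad) {
      G_h[tissue] + G_c[tissue] * smooth_heaviside(c_e[tissue], c_crit[tissue], config$beta)
    } else G_h[tissue]
    theta_new <- theta - rate * config$dt
    nclamp <- sum(theta_new < config$theta_floor)
    if (nclamp > 0) {
      clamped <- clamped + nclamp
      theta_new <- pmax(theta_new, config$theta_floor)
    }
    # equilibrium with automatic bisection of the atrophy increment
    solve_sub <- function(th_from, th_to, u0, depth) {
      tryCatch({
        sol <- solve_equilibrium(mesh, th_to, mat, u_init = u0,
                                 dirichlet = config$dirichlet,
                                 tol = config$newton_tol,
                                 max_iter = config$newton_max_iter, fem = fem)
        list(u = sol$u, iters = sol$iterations, res = sol$residual)
      }, error = function(e) {
        if (depth >= 4) stop_atrophy("step %d (t=%.2f yr): %s", k, t, conditionMessage(e))
        th_mid <- (th_from + th_to) / 2
        s1 <- solve_sub(th_from, th_mid, u0, depth + 1L)
        s2 <- solve_sub(th_mid, th_to, s1$u, depth + 1L)
        list(u = s2$u, iters = s1$iters + s2$iters, res = s2$res)
      })
    }
    sol <- solve_sub(theta, theta_new, u, 0L)
    theta <- theta_new
    u <- sol$u
    convlog[[k]] <- c(step = k, time = t, iterations = sol$iters, residual = sol$res)
    times[k + 1L] <- t
    record(k + 1L)
    if (k %% config$output_every == 0 || k == nsteps) snap(t)
    if (!quiet && k %% 50 == 0)
      message(sprintf("t = %.1f yr: min theta %.4f, max c %.3f", t, min(theta), max_c[k + 1L]))
  }
  structure(list(
    mesh = mesh, mat = mat, config = config,
    spreading = if (ad) spreading else NULL,
    times = times, volumes = vols, sulci_volumes = sul,
    min_theta = min_theta, mean_c = mean_c, max_c = max_c,
    theta_final = theta, c_final = if (ad) cf$values else NULL,
    u_final = u, snapshots = snapshots,
    convergence = do.call(rbind, convlog), clamped_points = clamped
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> mode=%s, t_end=%g yr, dt=%g yr, %d steps\n",
              x$config$mode, x$config$t_end, x$config$dt, length(x$times) - 1L))
  cat(sprintf("  min atrophy factor: %.4f; max concentration: %.3f\n",
              min(x$min_theta), max(x$max_c)))
  invisible(x)
}

#' Per-region deformed volume time series
#'
#' @param result a `simulation_result`.
#' @return Data frame with `time` and one column per region (mm^dim).
#' @export
region_volume_series <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  data.frame(time = result$times, result$volumes, check.names = FALSE)
}
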