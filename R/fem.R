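# Linear simplicial finite-element core (dimension-agnostic: P1 triangles
# or tetrahedra, single-point quadrature). Precomputes constant shape-
# function gradients per element and exposes vectorized assembly of
# diffusion stiffness and lumped mass.

# Shape-function gradients G[e, a, J] (a = 1..dim+1 local node, J spatial),
# plus reference measures V[e].
fem_gradients <- function(mesh) {
  X <- mesh$nodes
  el <- mesh$elements
  d <- mesh$dim
  ne <- nrow(el)
  if (d == 2L) {
    d11 <- X[el[, 2], 1] - X[el[, 1], 1]; d12 <- X[el[, 2], 2] - X[el[, 1], 2]
    d21 <- X[el[, 3], 1] - X[el[, 1], 1]; d22 <- X[el[, 3], 2] - X[el[, 1], 2]
    det <- d11 * d22 - d12 * d21
    G <- array(0, c(ne, 3, 2))
    G[, 2, 1] <- d22 / det;  G[, 2, 2] <- -d21 / det
    G[, 3, 1] <- -d12 / det; G[, 3, 2] <- d11 / det
    G[, 1, ] <- -(G[, 2, ] + G[, 3, ])
    list(G = G, V = det / 2)
  } else {
    D <- array(0, c(ne, 3, 3))
    for (k in 1:3) for (J in 1:3)
      D[, k, J] <- X[el[, k + 1L], J] - X[el[, 1], J]
    det <- D[, 1, 1] * (D[, 2, 2] * D[, 3, 3] - D[, 2, 3] * D[, 3, 2]) -
      D[, 1, 2] * (D[, 2, 1] * D[, 3, 3] - D[, 2, 3] * D[, 3, 1]) +
      D[, 1, 3] * (D[, 2, 1] * D[, 3, 2] - D[, 2, 2] * D[, 3, 1])
    # inverse via cofactors: (D^-1)[J,k] = cof(D)[k,J] / det
    Dinv <- array(0, c(ne, 3, 3))  # Dinv[, J, k]
    cof <- function(r1, r2, c1, c2) D[, r1, c1] * D[, r2, c2] - D[, r1, c2] * D[, r2, c1]
    Dinv[, 1, 1] <- cof(2, 3, 2, 3); Dinv[, 2, 1] <- -cof(2, 3, 1, 3); Dinv[, 3, 1] <- cof(2, 3, 1, 2)
    Dinv[, 1, 2] <- -cof(1, 3, 2, 3); Dinv[, 2, 2] <- cof(1, 3, 1, 3); Dinv[, 3, 2] <- -cof(1, 3, 1, 2)
    Dinv[, 1, 3] <- cof(1, 2, 2, 3); Dinv[, 2, 3] <- -cof(1, 2, 1, 3); Dinv[, 3, 3] <- cof(1, 2, 1, 2)
    Dinv <- Dinv / as.vector(det)
    G <- array(0, c(ne, 4, 3))
    for (k in 1:3) for (J in 1:3) G[, k + 1L, J] <- Dinv[, J, k]
    G[, 1, ] <- -(G[, 2, ] + G[, 3, ] + G[, 4, ])
    list(G = G, V = det / 6)
  }
}

# sparse diffusion stiffness with per-element coefficient:
# K[i,j] = sum_e coef_e V_e sum_J G[e,a,J] G[e,b,J]
assemble_diffusion <- function(mesh, fem, coef) {
  el <- mesh$elements
  d1 <- ncol(el)
  n <- nrow(mesh$nodes)
  ii <- jj <- integer(0); xx <- numeric(0)
  w <- coef * fem$V
  trip_i <- vector("list", d1 * d1)
  trip_j <- vector("list", d1 * d1)
  trip_x <- vector("list", d1 * d1)
  k <- 0L
  for (a in seq_len(d1)) for (b in seq_len(d1)) {
    k <- k + 1L
    gg <- rowSums(fem$G[, a, , drop = FALSE] * fem$G[, b, , drop = FALSE], dims = 1)
    trip_i[[k]] <- el[, a]; trip_j[[k]] <- el[, b]; trip_x[[k]] <- w * gg
  }
  Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j), x = unlist(trip_x),
                       dims = c(n, n))
}

# lumped mass vector: M[i] = sum_{e ∋ i} coef_e V_e / (dim+1)
lumped_mass <- function(mesh, fem, coef = 1) {
  el <- mesh$elements
  d1 <- ncol(el)
  w <- rep(coef, length.out = nrow(el)) * fem$V / d1
  M <- numeric(nrow(mesh$nodes))
  for (a in seq_len(d1)) {
    s <- rowsum(w, el[, a])
    M[as.integer(rownames(s))] <- M[as.integer(rownames(s))] + s[, 1]
  }
  M
}
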