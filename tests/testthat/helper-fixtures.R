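# Shared fixtures, built in code and cached per test session.

# coarse phantom for cheap unit tests (~1.5k elements)
coarse_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_brain_phantom(phantom_params(target_edge_length = 4))
    cache
  }
})

# default study phantom (the ~5k-element mesh the coupled runs use)
study_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_brain_phantom(phantom_params())
    cache
  }
})

# full 40-year coupled runs on the study phantom, one per mode, cached so
# several acceptance blocks can share them
study_run <- local({
  cache <- new.env()
  function(mode) {
    if (is.null(cache[[mode]])) {
      mat <- default_materials()
      cache[[mode]] <- run_simulation(
        study_phantom(), mat,
        simulation_config(t_end = 40, dt = 0.1, mode = mode),
        spreading = spreading_params(mat))
    }
    cache[[mode]]
  }
})

# random proper rotation matrix
random_rotation <- function(d) {
  qr_ <- qr(matrix(rnorm(d * d), d))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# random admissible deformation gradient (det > 0)
random_F <- function(d, spread = 0.15) {
  repeat {
    F <- diag(d) + matrix(rnorm(d * d, 0, spread), d)
    if (det(F) > 0.2) return(F)
  }
}
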