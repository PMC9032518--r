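# Parametric synthetic brain phantom.
#
# The phantom replaces a subject-specific MRI-derived mesh with a
# coronal-slice analog built from nested star-shaped rings: an elliptical
# ventricular cavity (meshed as a solid subdomain), a white-matter core
# whose outer boundary is a sinusoidally folded curve, a gray-matter ribbon
# of constant thickness obtained by offsetting the WM boundary outward
# along its normal (mirroring the "inflate WM by a constant thickness"
# construction), and an outer CSF layer whose exterior surface anchors the
# model. A hippocampal subregion is carved out of WM adjacent to the
# ventricular boundary, and the inter-gyral fluid is partitioned into named
# sulcal pockets so sulcal widening can be summed per sulcus.

#' Phantom generation parameters
#'
#' All lengths in mm. Defaults give a ~5k-element coronal-slice analog:
#' a 3 mm cortical ribbon, a 5 mm CSF layer, five gyral folds (hence five
#' inter-gyral sulcal pockets, matching the five named sulci tracked for
#' sulcal widening), and a target edge length inside the 2.0-2.3 mm band.
#' The hippocampal subregion is deliberately generous (a crescent of WM
#' relabeled around the inferior ventricular boundary, standing in for the
#' whole medial-temporal complex): its radius is set at the Fisher length
#' `sqrt(d / alpha)` of the default spreading parameters (~12.9 mm) so the
#' seeded biomarker survives diffusive dilution and reaches the critical
#' concentration within a 40-year simulation, as a smaller seed at this
#' domain scale would never activate the accelerated-atrophy pathway.
#'
#' @param outer_radius mean radius of the folded WM/GM interface (mm).
#' @param csf_thickness CSF layer thickness (mm); its outer surface carries
#'   the zero-displacement anchor.
#' @param csf_smoothing how much the gyral fold amplitude decays across the
#'   CSF layer (mm): the outer CSF boundary is a partially smoothed
#'   envelope of the pial folds, so sulcal troughs hold thicker fluid
#'   wedges than gyral crests. NULL (default) picks
#'   `min(csf_thickness/2, fold_amplitude/2)`, the most smoothing
#'   compatible with keeping element edges inside the target band.
#' @param cortical_thickness GM ribbon thickness (mm), spatially constant at
#'   generation time.
#' @param n_folds number of sinusoidal gyral folds (0 gives circular annuli).
#' @param fold_amplitude radial amplitude of the folds (mm).
#' @param fold_gap minimum admissible gap between adjacent gyral walls (mm);
#'   must be > 0 (no self-contact of the pial surface).
#' @param ventricle_semiaxes length-2 vector, semi-axes of the elliptical
#'   ventricular cavity (mm).
#' @param hippocampus_center length-2 vector, center of the hippocampal
#'   subregion (mm); must sit adjacent to the ventricular boundary.
#' @param hippocampus_radius radius of the hippocampal subregion (mm).
#' @param target_edge_length target mesh edge length (mm).
#' @param seed integer, recorded for provenance (the generator is fully
#'   deterministic given the parameters).
#' @param dimension 2 for the slice phantom, 3 for an extruded quasi-3D slab.
#' @param slab_layers number of element layers when `dimension = 3`.
#'
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(outer_radius = 52, csf_thickness = 5,
                           csf_smoothing = NULL,
                           cortical_thickness = 3, n_folds = 5,
                           fold_amplitude = 8, fold_gap = 2,
                           ventricle_semiaxes = c(14, 8),
                           hippocampus_center = c(0, -16),
                           hippocampus_radius = 14,
                           target_edge_length = 2.15,
                           seed = 1L, dimension = 2L,
                           slab_layers = 2L) {
  if (is.null(csf_smoothing))
    csf_smoothing <- min(csf_thickness / 2, fold_amplitude / 2)
  p <- list(outer_radius = outer_radius, csf_thickness = csf_thickness,
            csf_smoothing = csf_smoothing,
            cortical_thickness = cortical_thickness, n_folds = as.integer(n_folds),
            fold_amplitude = fold_amplitude, fold_gap = fold_gap,
            ventricle_semiaxes = ventricle_semiaxes,
            hippocampus_center = hippocampus_center,
            hippocampus_radius = hippocampus_radius,
            target_edge_length = target_edge_length,
            seed = as.integer(seed), dimension = as.integer(dimension),
            slab_layers = as.integer(slab_layers))
  class(p) <- "phantom_params"
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  if (!p$dimension %in% c(2L, 3L)) stop_atrophy("dimension must be 2 or 3")
  if (p$fold_gap <= 0)
    stop_atrophy("fold_gap must be > 0: a non-positive gap would allow self-contact of the pial surface")
  if (p$target_edge_length <= 0) stop_atrophy("target_edge_length must be > 0")
  if (p$csf_smoothing < 0 || p$csf_smoothing >= p$csf_thickness)
    stop_atrophy("csf_smoothing must lie in [0, csf_thickness): the smoothed envelope would otherwise touch the pial crests")
  if (p$n_folds < 0) stop_atrophy("n_folds must be >= 0")
  if (any(p$ventricle_semiaxes <= 0)) stop_atrophy("ventricle_semiaxes must be > 0")
  if (p$outer_radius - p$fold_amplitude <= max(p$ventricle_semiaxes) + p$hippocampus_radius)
    stop_atrophy("infeasible geometry: WM band too thin for the ventricle and hippocampus (outer_radius - fold_amplitude must exceed max(ventricle_semiaxes) + hippocampus_radius)")
  # outward-offset regularity: at concave fold sections the offset distance
  # (cortex + CSF) must stay below the local radius of curvature
  if (p$n_folds > 0 && p$fold_amplitude > 0) {
    phi <- seq(0, 2 * pi, length.out = 2048)
    r <- p$outer_radius + p$fold_amplitude * cos(p$n_folds * phi)
    r1 <- -p$fold_amplitude * p$n_folds * sin(p$n_folds * phi)
    r2 <- -p$fold_amplitude * p$n_folds^2 * cos(p$n_folds * phi)
    kappa <- (r^2 + 2 * r1^2 - r * r2) / (r^2 + r1^2)^1.5
    D <- p$cortical_thickness + p$csf_thickness
    if (min(1 + D * kappa) <= 0.05)
      stop_atrophy("infeasible geometry: folds intersect when offset by cortex+CSF thickness (%.1f mm); reduce fold_amplitude or n_folds", D)
    # inter-gyral wall gap on the pial surface
    pial <- wm_offset_curve(p, phi, p$cortical_thickness)
    sub <- seq(1, length(phi), by = 8)
    pr <- pial[sub, , drop = FALSE]
    ang <- phi[sub]
    dphi <- abs(outer(ang, ang, "-"))
    dphi <- pmin(dphi, 2 * pi - dphi)
    far <- dphi > pi / (1.5 * p$n_folds)
    if (any(far)) {
      dd <- as.matrix(stats::dist(pr))
      gap <- min(dd[far])
      if (gap < p$fold_gap)
        stop_atrophy("infeasible geometry: minimum gap between gyral walls (%.2f mm) is below fold_gap (%.2f mm)", gap, p$fold_gap)
    }
  }
  invisible(p)
}

# folded WM/GM interface in polar form and its outward-normal offsets
wm_radius <- function(p, phi) p$outer_radius + p$fold_amplitude * cos(p$n_folds * phi)

wm_offset_curve <- function(p, phi, dist) {
  if (p$n_folds == 0 || p$fold_amplitude == 0) {
    r <- p$outer_radius + dist
    return(cbind(r * cos(phi), r * sin(phi)))
  }
  r <- wm_radius(p, phi)
  r1 <- -p$fold_amplitude * p$n_folds * sin(p$n_folds * phi)
  er <- cbind(cos(phi), sin(phi))
  ep <- cbind(-sin(phi), cos(phi))
  nhat <- (r * er - r1 * ep) / sqrt(r^2 + r1^2)
  r * er + dist * nhat
}

curve_length <- function(coords) {
  polygon_perimeter(coords[, 1], coords[, 2])
}

ring_count <- function(L, h) 2L * max(4L, round(L / (2 * h)))

# resample a dense closed polyline (first point kept) to n points at
# uniform arc length; keeps generation deterministic and edge lengths even
resample_ring <- function(dense, h) {
  seg <- row_norms(rbind(dense[-1, , drop = FALSE], dense[1, , drop = FALSE]) - dense)
  L <- sum(seg)
  n <- ring_count(L, h)
  s_cum <- c(0, cumsum(seg))
  targets <- L * (seq_len(n) - 1L) / n
  xs <- stats::approx(s_cum, c(dense[, 1], dense[1, 1]), xout = targets)$y
  ys <- stats::approx(s_cum, c(dense[, 2], dense[1, 2]), xout = targets)$y
  cbind(xs, ys)
}

# stitch two nested closed rings (inner CCW, outer CCW, both starting near
# the same angular origin) into a conforming triangle band; advances
# greedily along whichever ring yields the shorter connecting edge, which
# keeps stitch diagonals close to sqrt(gap^2 + spacing^2)
stitch_rings <- function(idxA, coA, idxB, coB) {
  nA <- length(idxA); nB <- length(idxB)
  if (nA == 1L) {
    j <- seq_len(nB)
    return(cbind(idxA, idxB[j], idxB[c(j[-1L], 1L)]))
  }
  idxAu <- c(idxA, idxA[1]); idxBu <- c(idxB, idxB[1])
  coAu <- rbind(coA, coA[1, ]); coBu <- rbind(coB, coB[1, ])
  tris <- matrix(0L, nA + nB, 3)
  i <- 1L; j <- 1L
  for (k in seq_len(nA + nB)) {
    dA <- if (i <= nA) sum((coAu[i + 1L, ] - coBu[j, ])^2) else Inf
    dB <- if (j <= nB) sum((coAu[i, ] - coBu[j + 1L, ])^2) else Inf
    if (dA <= dB) {
      tris[k, ] <- c(idxAu[i], idxBu[j], idxAu[i + 1L])
      i <- i + 1L
    } else {
      tris[k, ] <- c(idxAu[i], idxBu[j], idxBu[j + 1L])
      j <- j + 1L
    }
  }
  tris
}

ring_phis <- function(n) 2 * pi * (seq_len(n) - 1L) / n

#' Generate the labeled synthetic brain phantom
#'
#' Builds a conforming labeled simplicial mesh with a ventricular cavity
#' (meshed as a solid subdomain), a WM core with a folded outer boundary, a
#' GM ribbon of constant thickness, a CSF layer whose outer boundary is the
#' `"csf_outer"` anchor set, a hippocampal subregion adjacent to the
#' ventricle, and named per-sulcus fluid pockets.
#'
#' @param params a [phantom_params] object (or arguments for one).
#' @return A [labeled_mesh] (2D triangles, or tetrahedra when
#'   `params$dimension == 3`).
#' @export
build_brain_phantom <- function(params = phantom_params()) {
  if (!inherits(params, "phantom_params")) params <- do.call(phantom_params, params)
  p <- params
  h <- p$target_edge_length
  a <- p$ventricle_semiaxes[1]; b <- p$ventricle_semiaxes[2]

  ellipse <- function(phi, s = 1) cbind(s * a * cos(phi), s * b * sin(phi))

  phid <- seq(0, 2 * pi, length.out = 1025)[-1025]
  wm_dense <- wm_offset_curve(p, phid, 0)
  vent_dense <- ellipse(phid)

  mV <- max(2L, round(((a + b) / 2) / h))
  gap_mean <- mean(row_norms(wm_dense - vent_dense))
  mW <- max(2L, round(gap_mean / h))
  mG <- max(1L, round(p$cortical_thickness / h))
  mC <- max(1L, round(p$csf_thickness / h))

  rings <- list()   # each: list(coords, region_of_band_below)
  # ventricle interior rings (band below ring k is VENT)
  for (k in seq_len(mV)) {
    rings[[length(rings) + 1L]] <- list(coords = resample_ring(vent_dense * (k / mV), h),
                                        region = "VENT")
  }
  iv_boundary <- length(rings)
  # WM band rows: blend ventricle ellipse -> folded WM boundary
  for (k in seq_len(mW)) {
    s <- k / mW
    rings[[length(rings) + 1L]] <- list(
      coords = resample_ring((1 - s) * vent_dense + s * wm_dense, h), region = "WM")
  }
  i_wm <- length(rings)
  # GM ribbon rows: constant-thickness outward offset
  for (k in seq_len(mG)) {
    d <- p$cortical_thickness * k / mG
    rings[[length(rings) + 1L]] <- list(
      coords = resample_ring(wm_offset_curve(p, phid, d), h), region = "GM")
  }
  i_pial <- length(rings)
  # CSF rows: gradual transition from the folded pial surface towards a
  # partially smoothed outer envelope (fold amplitude decays by
  # csf_smoothing across the layer)
  for (k in seq_len(mC)) {
    s <- k / mC
    d <- p$cortical_thickness + p$csf_thickness * s
    pk <- p
    pk$fold_amplitude <- max(0, p$fold_amplitude - p$csf_smoothing * s)
    rings[[length(rings) + 1L]] <- list(
      coords = resample_ring(wm_offset_curve(pk, phid, d), h), region = "CSF")
  }
  i_outer <- length(rings)

  # assemble nodes: center node first, then rings
  nodes <- rbind(c(0, 0), do.call(rbind, lapply(rings, `[[`, "coords")))
  ring_idx <- list()
  off <- 1L
  for (k in seq_along(rings)) {
    nk <- nrow(rings[[k]]$coords)
    ring_idx[[k]] <- off + seq_len(nk)
    off <- off + nk
  }

  tris <- list(); regs <- list()
  # center fan
  tris[[1]] <- stitch_rings(1L, nodes[1, , drop = FALSE],
                            ring_idx[[1]], rings[[1]]$coords)
  regs[[1]] <- rep("VENT", nrow(tris[[1]]))
  for (k in seq_len(length(rings) - 1L)) {
    tr <- stitch_rings(ring_idx[[k]], rings[[k]]$coords,
                       ring_idx[[k + 1L]], rings[[k + 1L]]$coords)
    tris[[k + 1L]] <- tr
    regs[[k + 1L]] <- rep(rings[[k + 1L]]$region, nrow(tr))
  }
  elements <- do.call(rbind, tris)
  region <- match(do.call(c, regs), region_labels())

  # hippocampus: relabel WM elements near hippocampus_center
  ctr <- matrix(0, nrow(elements), 2)
  for (aa in 1:3) ctr <- ctr + nodes[elements[, aa], ]
  ctr <- ctr / 3
  hip <- region == match("WM", region_labels()) &
    row_norms(sweep(ctr, 2, p$hippocampus_center)) < p$hippocampus_radius
  if (!any(hip))
    stop_atrophy("hippocampus region is empty: hippocampus_center/radius do not intersect the WM band")
  region[hip] <- match("HIPPO", region_labels())
  vent_nodes <- unique(as.vector(elements[region == match("VENT", region_labels()), ]))
  hip_nodes <- unique(as.vector(elements[region == match("HIPPO", region_labels()), ]))
  if (!any(hip_nodes %in% vent_nodes))
    stop_atrophy("hippocampus is not adjacent to the ventricular boundary; move hippocampus_center closer to the ventricle")

  boundary_sets <- list(
    vent_boundary = as.integer(ring_idx[[iv_boundary]]),
    wm_surface = as.integer(ring_idx[[i_wm]]),
    pial = as.integer(ring_idx[[i_pial]]),
    csf_outer = as.integer(ring_idx[[i_outer]])
  )

  # sulcal pockets: CSF inside the convex hull of the pial surface,
  # partitioned by nearest inter-gyral trough
  sulci <- list()
  if (p$n_folds > 0) {
    pial_xy <- nodes[boundary_sets$pial, , drop = FALSE]
    hull <- pial_xy[grDevices::chull(pial_xy), , drop = FALSE]
    csf_ix <- which(region == match("CSF", region_labels()))
    inside <- points_in_convex_polygon(ctr[csf_ix, , drop = FALSE], hull)
    pocket_ix <- csf_ix[inside]
    if (length(pocket_ix)) {
      troughs <- (pi + 2 * pi * (seq_len(p$n_folds) - 1L)) / p$n_folds
      troughs <- sort(troughs %% (2 * pi))
      ang <- atan2(ctr[pocket_ix, 2], ctr[pocket_ix, 1]) %% (2 * pi)
      dmat <- abs(outer(ang, troughs, "-"))
      dmat <- pmin(dmat, 2 * pi - dmat)
      assign <- max.col(-dmat)
      nm <- sulcus_names(p$n_folds)
      sulci <- lapply(seq_len(p$n_folds), function(k) as.integer(pocket_ix[assign == k]))
      names(sulci) <- nm
      sulci <- sulci[vapply(sulci, length, integer(1)) > 0]
    }
  }

  mesh <- labeled_mesh(nodes, elements, region,
                       boundary_sets = boundary_sets, sulci = sulci,
                       target_edge = h)
  if (p$dimension == 3L)
    mesh <- extrude_mesh(mesh, n_layers = p$slab_layers, dz = h)
  mesh
}

sulcus_names <- function(n) {
  canonical <- c("sylvian", "superior_temporal", "central",
                 "intra_parietal", "superior_frontal")
  if (n <= 5) canonical[seq_len(n)]
  else c(canonical, sprintf("sulcus_%d", 6:n))
}

# vectorized point-in-convex-polygon (hull vertices in order)
points_in_convex_polygon <- function(pts, hull) {
  n <- nrow(hull)
  inside <- rep(TRUE, nrow(pts))
  or <- polygon_signed_area(hull[, 1], hull[, 2])
  for (k in seq_len(n)) {
    a <- hull[k, ]; b_ <- hull[if (k == n) 1L else k + 1L, ]
    cr <- (b_[1] - a[1]) * (pts[, 2] - a[2]) - (b_[2] - a[2]) * (pts[, 1] - a[1])
    inside <- inside & (if (or > 0) cr > 0 else cr < 0)
  }
  inside
}

#' Extrude a 2D triangle mesh into a quasi-3D tetrahedral slab
#'
#' Each prism (triangle x layer) is split into three tetrahedra with a
#' node-index diagonal rule that keeps the decomposition conforming across
#' neighboring prisms. Region labels and sulcal pockets are inherited per
#' layer; `"csf_outer"` becomes the entire exterior boundary of the slab.
#'
#' @param mesh a 2D [labeled_mesh].
#' @param n_layers number of element layers.
#' @param dz layer thickness (mm).
#' @return A 3D [labeled_mesh].
#' @export
extrude_mesh <- function(mesh, n_layers = 2L, dz = mesh$target_edge) {
  stopifnot(mesh$dim == 2L)
  n2 <- nrow(mesh$nodes)
  zs <- dz * (0:n_layers)
  nodes3 <- do.call(rbind, lapply(zs, function(z) cbind(mesh$nodes, z)))
  el <- mesh$elements
  # rotate each triangle so its smallest node index comes first
  rot <- max.col(-matrix(el, ncol = 3), ties.method = "first")  # column of min per row
  el_r <- el
  el_r[rot == 2L, ] <- el[rot == 2L, c(2, 3, 1)]
  el_r[rot == 3L, ] <- el[rot == 3L, c(3, 1, 2)]
  a <- el_r[, 1]; b_ <- el_r[, 2]; c_ <- el_r[, 3]
  tets <- list(); regs <- list(); par <- list()
  for (l in seq_len(n_layers)) {
    lo <- (l - 1L) * n2; hi <- l * n2
    A <- a + hi; B <- b_ + hi; C <- c_ + hi
    ab <- a + lo; bb <- b_ + lo; cb <- c_ + lo
    bc <- b_ < c_
    # case b<c: tets (a,b,c,C), (a,b,C,B), (a,B,C,A)
    # case c<b: tets (a,b,c,B), (a,c,C,B), (a,C,A,B)
    t1 <- cbind(ab, bb, cb, ifelse(bc, C, B))
    t2 <- matrix(0L, nrow(el), 4)
    t3 <- matrix(0L, nrow(el), 4)
    t2[bc, ] <- cbind(ab, bb, C, B)[bc, ]
    t3[bc, ] <- cbind(ab, B, C, A)[bc, ]
    t2[!bc, ] <- cbind(ab, cb, C, B)[!bc, ]
    t3[!bc, ] <- cbind(ab, C, A, B)[!bc, ]
    tets[[l]] <- rbind(t1, t2, t3)
    regs[[l]] <- rep(mesh$region, 3L)
    par[[l]] <- rep(seq_len(nrow(el)), 3L)
  }
  elements <- do.call(rbind, tets)
  region <- do.call(c, regs)
  parent <- do.call(c, par)
  m3 <- list(nodes = nodes3, elements = elements, dim = 3L)
  v <- element_measures(structure(c(m3, list(region = region)), class = "labeled_mesh"))
  swap <- v < 0
  elements[swap, c(3, 4)] <- elements[swap, c(4, 3)]

  layer_nodes <- function(ids) as.integer(outer(ids, (0:n_layers) * n2, "+"))
  bsets <- lapply(mesh$boundary_sets, layer_nodes)
  tmp <- labeled_mesh(nodes3, elements, region, boundary_sets = list(),
                      sulci = list(), target_edge = mesh$target_edge)
  bf <- subset_boundary_facets(tmp, seq_len(nrow(elements)))
  bsets$csf_outer <- sort(unique(as.vector(bf)))
  sulci3 <- lapply(mesh$sulci, function(ix) {
    as.integer(which(parent %in% ix))
  })
  labeled_mesh(nodes3, elements, region, boundary_sets = bsets,
               sulci = sulci3, target_edge = mesh$target_edge)
}

#' Structured disk mesh (single tissue region)
#'
#' Concentric-ring triangulation of a disk, labeled GM throughout; useful
#' as a convex reference domain for morphometry oracles.
#'
#' @param radius disk radius (mm).
#' @param h target edge length (mm).
#' @return A 2D [labeled_mesh] with boundary set `"csf_outer"` on the rim.
#' @export
mesh_disk <- function(radius = 30, h = 2) {
  m <- max(2L, round(radius / h))
  rings <- lapply(seq_len(m), function(k) {
    r <- radius * k / m
    nk <- ring_count(2 * pi * r, h)
    phi <- ring_phis(nk)
    cbind(r * cos(phi), r * sin(phi))
  })
  nodes <- rbind(c(0, 0), do.call(rbind, rings))
  ring_idx <- list(); off <- 1L
  for (k in seq_len(m)) {
    nk <- nrow(rings[[k]]); ring_idx[[k]] <- off + seq_len(nk); off <- off + nk
  }
  tris <- list(stitch_rings(1L, nodes[1, , drop = FALSE], ring_idx[[1]], rings[[1]]))
  for (k in seq_len(m - 1L)) {
    tris[[k + 1L]] <- stitch_rings(ring_idx[[k]], rings[[k]],
                                   ring_idx[[k + 1L]], rings[[k + 1L]])
  }
  elements <- do.call(rbind, tris)
  labeled_mesh(nodes, elements, rep(match("GM", region_labels()), nrow(elements)),
               boundary_sets = list(csf_outer = as.integer(ring_idx[[m]])),
               target_edge = h)
}

#' Structured annulus mesh
#'
#' Triangulated annulus with a true interior cavity (unmeshed hole);
#' labeled GM. Boundary sets: `"cavity"` (inner rim) and `"csf_outer"`
#' (outer rim).
#'
#' @param r_in,r_out inner and outer radii (mm).
#' @param h target edge length (mm).
#' @param region region label for all elements.
#' @return A 2D [labeled_mesh].
#' @export
mesh_annulus <- function(r_in = 10, r_out = 30, h = 2, region = "GM") {
  m <- max(2L, round((r_out - r_in) / h))
  rings <- lapply(0:m, function(k) {
    r <- r_in + (r_out - r_in) * k / m
    nk <- ring_count(2 * pi * r, h)
    phi <- ring_phis(nk)
    cbind(r * cos(phi), r * sin(phi))
  })
  nodes <- do.call(rbind, rings)
  ring_idx <- list(); off <- 0L
  for (k in seq_len(m + 1L)) {
    nk <- nrow(rings[[k]]); ring_idx[[k]] <- off + seq_len(nk); off <- off + nk
  }
  tris <- list()
  for (k in seq_len(m)) {
    tris[[k]] <- stitch_rings(ring_idx[[k]], rings[[k]],
                              ring_idx[[k + 1L]], rings[[k + 1L]])
  }
  elements <- do.call(rbind, tris)
  labeled_mesh(nodes, elements, rep(match(region, region_labels()), nrow(elements)),
               boundary_sets = list(cavity = as.integer(ring_idx[[1]]),
                                    csf_outer = as.integer(ring_idx[[m + 1L]])),
               target_edge = h)
}

#' Structured rectangular strip mesh
#'
#' Right-triangle mesh of a `length_x` by `width_y` strip, labeled WM;
#' used e.g. for travelling-wave experiments on a quasi-1D bar.
#'
#' @param length_x,width_y strip dimensions (mm).
#' @param h target edge length (mm).
#' @param region region label for all elements.
#' @param crossed split each grid cell into four triangles through a
#'   center node, giving a mesh that is exactly mirror-symmetric about
#'   both midlines (useful for symmetry checks).
#' @return A 2D [labeled_mesh] with boundary sets `"left"`, `"right"`,
#'   and `"csf_outer"` (whole boundary).
#' @export
mesh_strip <- function(length_x = 200, width_y = 2, h = 1, region = "WM",
                       crossed = FALSE) {
  nx <- max(2L, round(length_x / h)); ny <- max(1L, round(width_y / h))
  xs <- seq(0, length_x, length.out = nx + 1L)
  ys <- seq(0, width_y, length.out = ny + 1L)
  nodes <- as.matrix(expand.grid(x = xs, y = ys))
  id <- function(i, j) i + (nx + 1L) * (j - 1L)   # i in 1..nx+1, j in 1..ny+1
  tris <- list()
  if (crossed) {
    xc <- (xs[-1] + xs[-(nx + 1L)]) / 2
    yc <- (ys[-1] + ys[-(ny + 1L)]) / 2
    centers <- as.matrix(expand.grid(x = xc, y = yc))
    cid <- function(i, j) nrow(nodes) + i + nx * (j - 1L)
    nodes2 <- rbind(nodes, centers)
    for (j in seq_len(ny)) {
      i <- seq_len(nx)
      n00 <- id(i, j); n10 <- id(i + 1L, j); n01 <- id(i, j + 1L)
      n11 <- id(i + 1L, j + 1L); nc <- cid(i, j)
      tris[[j]] <- rbind(cbind(n00, n10, nc), cbind(n10, n11, nc),
                         cbind(n11, n01, nc), cbind(n01, n00, nc))
    }
    nodes <- nodes2
  } else {
    for (j in seq_len(ny)) {
      i <- seq_len(nx)
      n00 <- id(i, j); n10 <- id(i + 1L, j); n01 <- id(i, j + 1L)
      n11 <- id(i + 1L, j + 1L)
      tris[[j]] <- rbind(cbind(n00, n10, n11), cbind(n00, n11, n01))
    }
  }
  elements <- do.call(rbind, tris)
  left <- which(nodes[, 1] == 0)
  right <- which(nodes[, 1] == length_x)
  outer_b <- which(nodes[, 1] %in% c(0, length_x) | nodes[, 2] %in% c(0, width_y))
  labeled_mesh(nodes, elements, rep(match(region, region_labels()), nrow(elements)),
               boundary_sets = list(left = as.integer(left), right = as.integer(right),
                                    csf_outer = as.integer(outer_b)),
               target_edge = h)
}
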