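#' Labeled simplicial mesh
#'
#' Container for the spatial domain: a conforming simplicial mesh (triangles
#' in 2D, tetrahedra in 3D) with a region label per element and named
#' boundary node sets. Regions partition the element set into white matter
#' (WM), gray matter (GM), hippocampus (HIPPO), ventricles (VENT) and
#' cerebrospinal fluid (CSF). Sulcal fluid pockets are stored as named
#' element sets so sulcal widening can be summed per sulcus.
#'
#' @param nodes numeric matrix, one row per node (mm), 2 or 3 columns.
#' @param elements integer matrix, one row per simplex, `dim + 1` columns.
#' @param region integer vector (1..5) or character vector of region labels,
#'   one entry per element.
#' @param boundary_sets named list of integer node-index vectors. Must
#'   contain `"csf_outer"`.
#' @param sulci named list of element-index vectors (may be empty).
#' @param target_edge target edge length used at generation time (mm), or NA.
#'
#' @return An object of class `labeled_mesh`.
#' @export
labeled_mesh <- function(nodes, elements, region,
                         boundary_sets = list(), sulci = list(),
                         target_edge = NA_real_) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  dimnames(nodes) <- NULL
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  dimnames(elements) <- NULL
  dim <- ncol(nodes)
  if (!dim %in% c(2L, 3L)) stop_atrophy("mesh must be 2D or 3D, got %d coordinates", dim)
  if (ncol(elements) != dim + 1L)
    stop_atrophy("elements must have %d nodes per simplex in %dD", dim + 1L, dim)
  if (is.character(region)) region <- match(region, region_labels())
  region <- as.integer(region)
  if (length(region) != nrow(elements))
    stop_atrophy("region labels (%d) must match element count (%d)",
                 length(region), nrow(elements))
  if (anyNA(region) || any(region < 1L | region > 5L))
    stop_atrophy("region labels must be in {%s}", paste(region_labels(), collapse = ", "))
  mesh <- structure(list(
    nodes = nodes, elements = elements, region = region,
    region_names = region_labels(),
    boundary_sets = boundary_sets, sulci = sulci,
    dim = dim, target_edge = target_edge
  ), class = "labeled_mesh")
  v <- element_measures(mesh)
  if (any(v <= 0))
    stop_atrophy("mesh has %d elements with non-positive measure (first: element %d)",
                 sum(v <= 0), which(v <= 0)[1])
  mesh
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cat(sprintf("<labeled_mesh> %dD: %d nodes, %d elements\n",
              x$dim, nrow(x$nodes), nrow(x$elements)))
  tab <- table(factor(x$region_names[x$region], levels = x$region_names))
  cat("  elements by region:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (length(x$sulci))
    cat("  sulcal pockets:", paste(names(x$sulci), collapse = ", "), "\n")
  if (length(x$boundary_sets))
    cat("  boundary sets:", paste(names(x$boundary_sets), collapse = ", "), "\n")
  invisible(x)
}

#' Signed element measures
#'
#' Area (2D) or volume (3D) of every simplex; positive for correctly
#' oriented elements. `nodes` may override the reference coordinates, e.g.
#' to measure a deformed configuration.
#'
#' @param mesh a [labeled_mesh].
#' @param nodes optional node coordinate matrix replacing `mesh$nodes`.
#' @return Numeric vector, one signed measure per element (mm^dim).
#' @export
element_measures <- function(mesh, nodes = NULL) {
  X <- nodes %||% mesh$nodes
  el <- mesh$elements
  if (mesh$dim == 2L) {
    x1 <- X[el[, 1], , drop = FALSE]; x2 <- X[el[, 2], , drop = FALSE]
    x3 <- X[el[, 3], , drop = FALSE]
    0.5 * ((x2[, 1] - x1[, 1]) * (x3[, 2] - x1[, 2]) -
             (x3[, 1] - x1[, 1]) * (x2[, 2] - x1[, 2]))
  } else {
    a <- X[el[, 2], ] - X[el[, 1], ]
    b <- X[el[, 3], ] - X[el[, 1], ]
    c_ <- X[el[, 4], ] - X[el[, 1], ]
    (a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
       a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
       a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
  }
}

element_centroids <- function(mesh, nodes = NULL) {
  X <- nodes %||% mesh$nodes
  el <- mesh$elements
  out <- matrix(0, nrow(el), mesh$dim)
  for (a in seq_len(ncol(el))) out <- out + X[el[, a], , drop = FALSE]
  out / ncol(el)
}

#' Total and per-region mesh measure
#'
#' @param mesh a [labeled_mesh].
#' @param nodes optional node coordinates (deformed configuration).
#' @return Named numeric vector of region measures (mm^2 in 2D, mm^3 in 3D),
#'   one entry per region present, plus attribute `"total"`.
#' @export
region_measures <- function(mesh, nodes = NULL) {
  v <- element_measures(mesh, nodes)
  out <- vapply(seq_along(mesh$region_names),
                function(r) sum(v[mesh$region == r]), numeric(1))
  names(out) <- mesh$region_names
  attr(out, "total") <- sum(v)
  out
}

# unique edges as 2-column matrix of node indices (sorted rows)
mesh_edges <- function(mesh) {
  el <- mesh$elements
  d1 <- ncol(el)
  pairs <- utils::combn(d1, 2)
  e <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k)
    cbind(el[, pairs[1, k]], el[, pairs[2, k]])))
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(e), , drop = FALSE]
}

#' Mesh quality diagnostics
#'
#' Reports edge-length range, aspect ratios, and minimum signed element
#' measure; optionally flags edges outside a target band, mirroring the
#' generation constraint of similarly sized elements.
#'
#' @param mesh a [labeled_mesh].
#' @param edge_band optional length-2 numeric: flag edges outside it (mm).
#' @return List with `min_edge`, `max_edge`, `mean_edge`, `min_measure`,
#'   `max_aspect`, `n_inverted`, and (if `edge_band` given) `n_edges_outside_band`.
#' @export
mesh_quality_report <- function(mesh, edge_band = NULL) {
  e <- mesh_edges(mesh)
  len <- row_norms(mesh$nodes[e[, 2], , drop = FALSE] - mesh$nodes[e[, 1], , drop = FALSE])
  v <- element_measures(mesh)
  # aspect ratio: longest element edge / smallest altitude (2D),
  # longest edge^dim / (dim! * measure) style normalization otherwise
  el <- mesh$elements
  d1 <- ncol(el)
  pairs <- utils::combn(d1, 2)
  elen <- sapply(seq_len(ncol(pairs)), function(k)
    row_norms(mesh$nodes[el[, pairs[2, k]], , drop = FALSE] -
                mesh$nodes[el[, pairs[1, k]], , drop = FALSE]))
  lmax <- apply(elen, 1, max)
  aspect <- if (mesh$dim == 2L) lmax^2 / (2 * abs(v)) else lmax^3 / (6 * abs(v))
  rep <- list(
    min_edge = min(len), max_edge = max(len), mean_edge = mean(len),
    min_measure = min(v), max_aspect = max(aspect),
    n_inverted = sum(v <= 0)
  )
  if (!is.null(edge_band)) {
    rep$edge_band <- edge_band
    rep$n_edges_outside_band <- sum(len < edge_band[1] | len > edge_band[2])
  }
  rep
}

# boundary facets of an element subset: facets used exactly once.
# Returns matrix of facet node indices (dim columns), oriented so the
# outward normal points away from the owning element's remaining node.
subset_boundary_facets <- function(mesh, elem_idx) {
  el <- mesh$elements[elem_idx, , drop = FALSE]
  d1 <- ncol(el)
  fl <- lapply(seq_len(d1), function(drop_a) el[, -drop_a, drop = FALSE])
  facets <- do.call(rbind, fl)
  opp <- do.call(c, lapply(seq_len(d1), function(drop_a) el[, drop_a]))
  owner <- rep(elem_idx, d1)
  key <- apply(facets, 1, function(r) paste(sort(r), collapse = "-"))
  cnt <- table(key)
  keep <- key %in% names(cnt)[cnt == 1L]
  facets <- facets[keep, , drop = FALSE]
  opp <- opp[keep]
  owner <- owner[keep]
  # orient outward
  X <- mesh$nodes
  if (mesh$dim == 2L) {
    t_ <- X[facets[, 2], , drop = FALSE] - X[facets[, 1], , drop = FALSE]
    nrm <- cbind(t_[, 2], -t_[, 1])          # right-hand normal of edge
    toin <- X[opp, , drop = FALSE] - X[facets[, 1], , drop = FALSE]
    flip <- rowSums(nrm * toin) > 0          # normal points inward -> flip
    facets[flip, ] <- facets[flip, c(2, 1)]
  } else {
    a <- X[facets[, 2], ] - X[facets[, 1], ]
    b <- X[facets[, 3], ] - X[facets[, 1], ]
    nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
    toin <- X[opp, ] - X[facets[, 1], ]
    flip <- rowSums(nrm * toin) > 0
    facets[flip, ] <- facets[flip, c(1, 3, 2)]
  }
  attr(facets, "owner") <- owner
  facets
}

# chain oriented boundary edges (2D) into closed loops of node indices
chain_boundary_loops <- function(edges) {
  loops <- list()
  used <- rep(FALSE, nrow(edges))
  # edges are oriented head -> tail; follow by matching tail to next head
  from <- edges[, 1]
  repeat {
    s <- which(!used)[1]
    if (is.na(s)) break
    loop <- c(edges[s, 1], edges[s, 2])
    used[s] <- TRUE
    repeat {
      nxt <- which(!used & from == loop[length(loop)])
      if (!length(nxt)) break
      nxt <- nxt[1]
      used[nxt] <- TRUE
      if (edges[nxt, 2] == loop[1]) break
      loop <- c(loop, edges[nxt, 2])
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Extract the boundary of a labeled region
#'
#' Returns the boundary of the union of all elements carrying the given
#' label(s): ordered closed contours in 2D (counter-clockwise for outer
#' loops, i.e. consistent outward normals), or an oriented triangulated
#' surface in 3D.
#'
#' @param mesh a [labeled_mesh].
#' @param label one or more region labels (e.g. `"WM"`, or
#'   `tissue_labels()` for the pial/tissue boundary).
#' @param nodes optional node coordinates (deformed configuration).
#' @return In 2D, a list of loops; each loop is a list with `nodes`
#'   (indices) and `coords` (closed-implicit coordinate matrix). Loops are
#'   sorted by decreasing enclosed |area| (outer loop first). In 3D, a list
#'   with `faces` (oriented triangles) and `nodes` (indices used).
#' @export
extract_region_boundary <- function(mesh, label, nodes = NULL) {
  r <- match(label, mesh$region_names)
  if (anyNA(r)) stop_atrophy("unknown region label(s): %s",
                             paste(label[is.na(r)], collapse = ", "))
  idx <- which(mesh$region %in% r)
  if (!length(idx)) stop_atrophy("no elements labeled %s", paste(label, collapse = "/"))
  X <- nodes %||% mesh$nodes
  facets <- subset_boundary_facets(mesh, idx)
  if (mesh$dim == 3L)
    return(list(faces = facets, nodes = sort(unique(as.vector(facets)))))
  loops <- chain_boundary_loops(facets)
  out <- lapply(loops, function(lp) {
    co <- X[lp, , drop = FALSE]
    list(nodes = lp, coords = co, area = polygon_signed_area(co[, 1], co[, 2]),
         length = polygon_perimeter(co[, 1], co[, 2]))
  })
  out[order(-abs(vapply(out, function(l) l$area, numeric(1))))]
}

# segment-segment proper intersection test for a closed polyline;
# returns TRUE if any two non-adjacent segments intersect
polyline_self_intersects <- function(coords) {
  n <- nrow(coords)
  j <- c(seq_len(n)[-1L], 1L)
  p <- coords
  q <- coords[j, , drop = FALSE]
  cp <- utils::combn(n, 2)
  i1 <- cp[1, ]; i2 <- cp[2, ]
  adj <- (i2 - i1 == 1L) | (i1 == 1L & i2 == n)
  i1 <- i1[!adj]; i2 <- i2[!adj]
  d1 <- q[i1, , drop = FALSE] - p[i1, , drop = FALSE]
  d2 <- q[i2, , drop = FALSE] - p[i2, , drop = FALSE]
  w <- p[i2, , drop = FALSE] - p[i1, , drop = FALSE]
  den <- d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]
  ok <- abs(den) > 1e-14
  t1 <- (w[, 1] * d2[, 2] - w[, 2] * d2[, 1]) / den
  t2 <- (w[, 1] * d1[, 2] - w[, 2] * d1[, 1]) / den
  any(ok & t1 > 0 & t1 < 1 & t2 > 0 & t2 < 1)
}
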