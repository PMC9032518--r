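# Morphometry of simulation outputs: region volume fractions, slice-wise
# gyrification index (exact polygon ratio in 2D, rasterized slices in 3D),
# two-way nearest-node cortical thickness, and per-sulcus widening.

#' Gyrification index of a closed polygonal contour
#'
#' Ratio of the exact contour length to the perimeter of its convex hull;
#' 1 for convex shapes, > 1 for folded ones.
#'
#' @param coords matrix of contour vertices in order (closed implicitly).
#' @return A single number >= 1 (up to discretization of the hull).
#' @export
polygon_gyrification_index <- function(coords) {
  hull <- coords[grDevices::chull(coords), , drop = FALSE]
  polygon_perimeter(coords[, 1], coords[, 2]) /
    polygon_perimeter(hull[, 1], hull[, 2])
}

#' Gyrification index profile
#'
#' In 2D the tissue domain (GM, WM, hippocampus, ventricles) is a polygon
#' and the GI is the exact ratio of its pial (exterior) contour length to
#' its convex-hull perimeter. In 3D the mesh is cut into slices along an
#' axis, each slice is rasterized to a binary tissue image at `pixel`
#' resolution, and the GI is the ratio of the extracted tissue contour
#' length to the hull perimeter of the tissue pixels. Slices without
#' tissue are reported as NA (absent, not zero).
#'
#' @param mesh a [labeled_mesh].
#' @param u optional displacement field (nodes x dim): GI of the deformed
#'   configuration.
#' @param n_slices number of slices in 3D (ignored in 2D).
#' @param axis slicing axis in 3D (1, 2 or 3; default 3, across the slab).
#' @param pixel rasterization pixel size in mm (3D only).
#' @return Object of class `gyrification_profile`: list with `positions`,
#'   `gi`, `mean`, `sd`.
#' @export
gyrification_index <- function(mesh, u = NULL, n_slices = 160, axis = 3L,
                               pixel = 0.5) {
  X <- mesh$nodes + (u %||% 0)
  if (mesh$dim == 2L) {
    loops <- extract_region_boundary(mesh, tissue_labels(), nodes = X)
    gi <- polygon_gyrification_index(loops[[1]]$coords)
    prof <- list(positions = 0, gi = gi, mean = gi, sd = NA_real_)
  } else {
    tis <- which(mesh$region %in% match(tissue_labels(), mesh$region_names))
    rng <- range(X[unique(as.vector(mesh$elements[tis, ])), axis])
    pos <- seq(rng[1], rng[2], length.out = n_slices + 2L)[-c(1, n_slices + 2L)]
    gi <- vapply(pos, function(s) slice_gi(mesh, X, tis, axis, s, pixel), numeric(1))
    prof <- list(positions = pos, gi = gi,
                 mean = mean(gi, na.rm = TRUE), sd = stats::sd(gi[!is.na(gi)]))
  }
  class(prof) <- "gyrification_profile"
  prof
}

#' @export
print.gyrification_profile <- function(x, ...) {
  cat(sprintf("<gyrification_profile> %d slice(s): mean GI %.3f%s\n",
              length(x$gi), x$mean,
              if (is.na(x$sd)) "" else sprintf(" +/- %.3f", x$sd)))
  invisible(x)
}

# rasterized GI of one 3D slice: binary tissue mask -> contour length over
# convex-hull perimeter of the tissue pixels
slice_gi <- function(mesh, X, tis, axis, s, pixel) {
  el <- mesh$elements[tis, , drop = FALSE]
  za <- matrix(X[el, axis], nrow = nrow(el))
  hit <- which(apply(za, 1, min) <= s & apply(za, 1, max) >= s)
  if (!length(hit)) return(NA_real_)
  inplane <- setdiff(1:3, axis)
  xs <- X[, inplane[1]]; ys <- X[, inplane[2]]
  rngx <- range(xs); rngy <- range(ys)
  gx <- seq(rngx[1] - pixel, rngx[2] + pixel, by = pixel)
  gy <- seq(rngy[1] - pixel, rngy[2] + pixel, by = pixel)
  mask <- matrix(0, length(gx), length(gy))
  zc <- X[, axis]
  for (e in hit) {
    nd <- el[e, ]
    bbx <- range(xs[nd]); bby <- range(ys[nd])
    ix <- which(gx >= bbx[1] - 1e-9 & gx <= bbx[2] + 1e-9)
    iy <- which(gy >= bby[1] - 1e-9 & gy <= bby[2] + 1e-9)
    if (!length(ix) || !length(iy)) next
    pts <- cbind(rep(gx[ix], length(iy)), rep(gy[iy], each = length(ix)))
    # barycentric point-in-tet test at slice coordinate s
    P <- cbind(pts[, 1], pts[, 2])
    Pe <- matrix(0, nrow(P), 3)
    Pe[, inplane[1]] <- P[, 1]; Pe[, inplane[2]] <- P[, 2]; Pe[, axis] <- s
    Tm <- t(cbind(X[nd[2], ] - X[nd[1], ], X[nd[3], ] - X[nd[1], ], X[nd[4], ] - X[nd[1], ]))
    lam <- t(solve(t(Tm), t(sweep(Pe, 2, X[nd[1], ]))))
    ok <- lam[, 1] >= -1e-9 & lam[, 2] >= -1e-9 & lam[, 3] >= -1e-9 &
      (lam[, 1] + lam[, 2] + lam[, 3]) <= 1 + 1e-9
    if (any(ok)) {
      idx <- cbind(rep(ix, length(iy)), rep(iy, each = length(ix)))[ok, , drop = FALSE]
      mask[idx] <- 1
    }
  }
  if (sum(mask) < 4) return(NA_real_)
  cl <- grDevices::contourLines(gx, gy, mask, levels = 0.5)
  if (!length(cl)) return(NA_real_)
  contour_len <- sum(vapply(cl, function(c_) {
    sum(sqrt(diff(c_$x)^2 + diff(c_$y)^2))
  }, numeric(1)))
  pix <- which(mask == 1, arr.ind = TRUE)
  pc <- cbind(gx[pix[, 1]], gy[pix[, 2]])
  hull <- pc[grDevices::chull(pc), , drop = FALSE]
  contour_len / polygon_perimeter(hull[, 1], hull[, 2])
}

#' Literature gyrification-index-vs-age reference curve
#'
#' Cross-sectional reference `GI(A) = a + b ln(A + c)` with a = 3.4,
#' b = -0.175, c = -2.9991 (age A in years), used as a comparison curve
#' for simulated gyrification loss.
#'
#' @param age age in years; must satisfy `age + c > 0` (age > 2.9991).
#' @return Reference GI value.
#' @export
cao_reference_gi <- function(age) {
  if (any(age - 2.9991 <= 0))
    stop_atrophy("reference GI curve is defined only for age > 2.9991 years")
  3.4 - 0.175 * log(age - 2.9991)
}

# nearest-neighbor index of each query row in ref rows, via a uniform
# grid-bucket search with expanding rings
nn_index <- function(query, ref) {
  nq <- nrow(query); nr <- nrow(ref)
  if (nr <= 64) return(nn_index_brute(query, ref))
  d <- ncol(ref)
  lo <- apply(rbind(ref, query), 2, min) - 1e-9
  hi <- apply(rbind(ref, query), 2, max) + 1e-9
  cell <- max((hi - lo)) / max(4, floor(nr^(1 / d)))
  key <- function(pts) {
    ik <- floor(sweep(pts, 2, lo) / cell)
    apply(ik, 1, paste, collapse = ",")
  }
  rk <- key(ref)
  buckets <- split(seq_len(nr), rk)
  qik <- floor(sweep(query, 2, lo) / cell)
  out <- integer(nq)
  for (q in seq_len(nq)) {
    best <- NA_integer_
    dbest <- Inf
    ring <- 0L
    repeat {
      offs <- as.matrix(expand.grid(rep(list(-ring:ring), d)))
      if (ring > 0) offs <- offs[apply(abs(offs), 1, max) == ring, , drop = FALSE]
      keys <- apply(sweep(offs, 2, qik[q, ], "+"), 1, paste, collapse = ",")
      cand <- unlist(buckets[keys], use.names = FALSE)
      if (length(cand)) {
        dd <- colSums((t(ref[cand, , drop = FALSE]) - query[q, ])^2)
        if (min(dd) < dbest) {
          dbest <- min(dd)
          best <- cand[which.min(dd)]
        }
      }
      # any point beyond ring r lies at distance >= r * cell from the query
      if (!is.na(best) && sqrt(dbest) <= ring * cell) break
      ring <- ring + 1L
      if (ring > 1e4) stop_atrophy("nearest-neighbor search failed")
    }
    out[q] <- best
  }
  out
}

# quadratic-cost oracle, exact; retained for testing the accelerated path
nn_index_brute <- function(query, ref) {
  vapply(seq_len(nrow(query)), function(q) {
    which.min(colSums((t(ref) - query[q, ])^2))
  }, integer(1))
}

#' Two-way nearest-node cortical thickness
#'
#' For each pial (outer GM surface) node `i`: find the nearest WM-surface
#' node `j` (distance `d_ij`), then the pial node `k` nearest to `j`
#' (distance `d_jk`); thickness is `t_c(i) = 0.5 (d_ij + d_jk)`.
#'
#' @param pial_surface matrix of pial node coordinates (n x dim).
#' @param wm_surface matrix of WM-surface node coordinates (m x dim).
#' @param brute use the quadratic-cost reference implementation.
#' @return Object of class `thickness_map`: list with `thickness` (per
#'   pial node, mm), `mean`, `min`, `max`.
#' @export
cortical_thickness <- function(pial_surface, wm_surface, brute = FALSE) {
  pial_surface <- as.matrix(pial_surface); wm_surface <- as.matrix(wm_surface)
  if (nrow(pial_surface) <= 2L || nrow(wm_surface) <= 2L)
    stop_atrophy("cortical_thickness: degenerate surface (need > 2 nodes)")
  nn <- if (brute) nn_index_brute else nn_index
  j <- nn(pial_surface, wm_surface)
  d_ij <- row_norms(pial_surface - wm_surface[j, , drop = FALSE])
  k <- nn(wm_surface[j, , drop = FALSE], pial_surface)
  d_jk <- row_norms(wm_surface[j, , drop = FALSE] - pial_surface[k, , drop = FALSE])
  t_c <- 0.5 * (d_ij + d_jk)
  structure(list(thickness = t_c, mean = mean(t_c), min = min(t_c), max = max(t_c)),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("<thickness_map> %d pial nodes: mean %.2f mm (range %.2f-%.2f)\n",
              length(x$thickness), x$mean, x$min, x$max))
  invisible(x)
}

# cortical thickness of a phantom mesh (optionally deformed)
mesh_cortical_thickness <- function(mesh, u = NULL, ...) {
  X <- mesh$nodes + (u %||% 0)
  cortical_thickness(X[mesh$boundary_sets$pial, , drop = FALSE],
                     X[mesh$boundary_sets$wm_surface, , drop = FALSE], ...)
}

#' Region volume fractions at a stored simulation step
#'
#' Deformed per-region volume divided by the denominator volume: `"brain"`
#' is WM+GM+HIPPO+VENT, `"intracranial"` additionally includes CSF. Both
#' conventions are offered because cross-sectional studies normalize
#' inconsistently; outputs are labeled with the denominator used.
#'
#' @param result a `simulation_result`.
#' @param step step index (1 = initial state; defaults to the last step).
#' @param denominator `"brain"` or `"intracranial"`.
#' @return Named vector of fractions (attributes: `denominator`, `time`).
#' @export
volume_fractions <- function(result, step = NULL,
                             denominator = c("brain", "intracranial")) {
  denominator <- match.arg(denominator)
  step <- step %||% length(result$times)
  v <- result$volumes[step, ]
  den <- if (denominator == "brain") sum(v[tissue_labels()]) else sum(v)
  if (den <= 0) stop_atrophy("volume_fractions: zero denominator volume")
  out <- v / den
  attr(out, "denominator") <- denominator
  attr(out, "time") <- result$times[step]
  out
}

#' Sulcal widening time series
#'
#' Deformed volume of each named sulcal fluid pocket per stored step, and
#' the percent change relative to the initial state.
#'
#' @param result a `simulation_result`.
#' @param sulcus_names subset of pocket names (default: all).
#' @return Data frame: `time`, `sulcus`, `volume`, `pct_change`.
#' @export
sulcal_widening <- function(result, sulcus_names = NULL) {
  sv <- result$sulci_volumes
  if (is.null(sv) || !ncol(sv))
    stop_atrophy("no sulcal pockets present in this mesh")
  sulcus_names <- sulcus_names %||% colnames(sv)
  bad <- setdiff(sulcus_names, colnames(sv))
  if (length(bad))
    stop_atrophy("unknown sulcus name(s): %s (available: %s)",
                 paste(bad, collapse = ", "), paste(colnames(sv), collapse = ", "))
  long <- do.call(rbind, lapply(sulcus_names, function(nm) {
    data.frame(time = result$times, sulcus = nm, volume = sv[, nm],
               pct_change = 100 * (sv[, nm] / sv[1, nm] - 1))
  }))
  rownames(long) <- NULL
  long
}

#' Aggregate morphometry report
#'
#' Computes, at the first and last stored step of a simulation: region
#' volume fractions under both denominators, the ventricular expansion
#' factor, the relative change of the hippocampal brain-volume fraction,
#' per-sulcus widening, the gyrification index, and cortical thickness
#' summaries (reference and deformed configurations).
#'
#' @param result a `simulation_result`.
#' @return Object of class `morphometry_report`.
#' @export
build_report <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  mesh <- result$mesh
  nlast <- length(result$times)
  fr <- function(step, den) volume_fractions(result, step, den)
  u0 <- matrix(0, nrow(mesh$nodes), mesh$dim)
  u1 <- result$u_final
  gi0 <- gyrification_index(mesh, u0)
  gi1 <- gyrification_index(mesh, u1)
  th <- if (!is.null(mesh$boundary_sets$pial) && !is.null(mesh$boundary_sets$wm_surface)) {
    list(young = mesh_cortical_thickness(mesh, u0),
         aged = mesh_cortical_thickness(mesh, u1))
  } else NULL
  vent0 <- unname(result$volumes[1, "VENT"])
  vent1 <- unname(result$volumes[nlast, "VENT"])
  # hippocampal fraction change under both denominator conventions: the
  # "brain" denominator itself deforms, the intracranial one is fixed by
  # the anchored outer boundary
  hip_chg <- vapply(c("brain", "intracranial"), function(den) {
    100 * (fr(nlast, den)[["HIPPO"]] / fr(1, den)[["HIPPO"]] - 1)
  }, numeric(1))
  sul <- if (ncol(result$sulci_volumes)) sulcal_widening(result) else NULL
  structure(list(
    mode = result$config$mode,
    t_end = result$times[nlast],
    fractions = list(
      brain_young = fr(1, "brain"), brain_aged = fr(nlast, "brain"),
      intracranial_young = fr(1, "intracranial"),
      intracranial_aged = fr(nlast, "intracranial")),
    ventricular_expansion_factor = vent1 / vent0,
    hippocampal_fraction_change_pct = hip_chg,
    sulcal_widening = sul,
    gi = list(young = gi0, aged = gi1),
    thickness = th
  ), class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat(sprintf("<morphometry_report> mode=%s, %g yr\n", x$mode, x$t_end))
  cat(sprintf("  ventricular expansion factor: %.3f\n", x$ventricular_expansion_factor))
  cat(sprintf("  hippocampal fraction change: %+.2f%% (brain), %+.2f%% (intracranial)\n",
              x$hippocampal_fraction_change_pct[["brain"]],
              x$hippocampal_fraction_change_pct[["intracranial"]]))
  cat(sprintf("  GI: young %.4f -> aged %.4f\n", x$gi$young$mean, x$gi$aged$mean))
  if (!is.null(x$thickness))
    cat(sprintf("  cortical thickness: young %.2f mm -> aged %.2f mm\n",
                x$thickness$young$mean, x$thickness$aged$mean))
  invisible(x)
}

#' Write a morphometry report to CSV + JSON
#'
#' Long-format CSV (`time`, `metric`, `item`, `value`) and a JSON summary.
#'
#' @param report a `morphometry_report`.
#' @param dir output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- list()
  add <- function(time, metric, item, value)
    rows[[length(rows) + 1L]] <<- data.frame(time = time, metric = metric,
                                             item = item, value = value)
  for (nm in names(report$fractions)) {
    f <- report$fractions[[nm]]
    t_ <- attr(f, "time")
    for (r in names(f)) add(t_, paste0("fraction_", attr(f, "denominator")), r, f[[r]])
  }
  add(report$t_end, "ventricular_expansion_factor", "VENT",
      report$ventricular_expansion_factor)
  for (den in names(report$hippocampal_fraction_change_pct))
    add(report$t_end, paste0("hippocampal_fraction_change_pct_", den), "HIPPO",
        report$hippocampal_fraction_change_pct[[den]])
  if (!is.null(report$sulcal_widening)) {
    sl <- report$sulcal_widening
    last <- sl[sl$time == max(sl$time), ]
    for (i in seq_len(nrow(last)))
      add(last$time[i], "sulcal_widening_pct", last$sulcus[i], last$pct_change[i])
  }
  add(0, "gyrification_index", "mean", report$gi$young$mean)
  add(report$t_end, "gyrification_index", "mean", report$gi$aged$mean)
  if (!is.null(report$thickness)) {
    add(0, "cortical_thickness_mm", "mean", report$thickness$young$mean)
    add(report$t_end, "cortical_thickness_mm", "mean", report$thickness$aged$mean)
  }
  long <- do.call(rbind, rows)
  csv <- file.path(dir, sprintf("morphometry_%s.csv", report$mode))
  utils::write.csv(long, csv, row.names = FALSE)
  js <- file.path(dir, sprintf("morphometry_%s.json", report$mode))
  jsonlite::write_json(list(
    mode = report$mode, t_end = report$t_end,
    ventricular_expansion_factor = report$ventricular_expansion_factor,
    hippocampal_fraction_change_pct = as.list(report$hippocampal_fraction_change_pct),
    gi_young = report$gi$young$mean, gi_aged = report$gi$aged$mean,
    thickness_young_mm = if (is.null(report$thickness)) NULL else report$thickness$young$mean,
    thickness_aged_mm = if (is.null(report$thickness)) NULL else report$thickness$aged$mean
  ), js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
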