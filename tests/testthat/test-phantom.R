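test_that("circular annuli reproduce analytic region areas and exact bookkeeping", {
  p <- phantom_params(n_folds = 0, fold_amplitude = 0)
  m <- build_brain_phantom(p)
  areas <- region_measures(m)
  a <- p$ventricle_semiaxes[1]; b <- p$ventricle_semiaxes[2]; R <- p$outer_radius
  expect_lt(abs(areas[["VENT"]] - pi * a * b) / (pi * a * b), 0.01)
  gm_exact <- pi * ((R + 3)^2 - R^2)
  csf_exact <- pi * ((R + 8)^2 - (R + 3)^2)
  wm_exact <- pi * R^2 - pi * a * b - areas[["HIPPO"]]
  expect_lt(abs(areas[["GM"]] - gm_exact) / gm_exact, 0.01)
  expect_lt(abs(areas[["CSF"]] - csf_exact) / csf_exact, 0.01)
  expect_lt(abs(areas[["WM"]] - wm_exact) / wm_exact, 0.01)
  # labeled measures partition the total measure to near machine precision
  expect_lt(abs(sum(areas) - attr(areas, "total")) / attr(areas, "total"), 1e-10)
})

test_that("default phantom is deterministic, conforming and well-shaped", {
  m1 <- build_brain_phantom(phantom_params(seed = 7))
  m2 <- build_brain_phantom(phantom_params(seed = 7))
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$elements, m2$elements)
  m <- study_phantom()
  expect_setequal(unique(m$region), 1:5)
  expect_true(all(element_measures(m) > 0))
  # all edges within half-to-double the target edge length
  q <- mesh_quality_report(m)
  h <- m$target_edge
  expect_gte(q$min_edge, 0.5 * h)
  expect_lte(q$max_edge, 2 * h)
  expect_identical(q$n_inverted, 0L)
  # csf_outer is the entire exterior boundary
  bf <- atrophysim:::subset_boundary_facets(m, seq_len(nrow(m$elements)))
  expect_setequal(unique(as.vector(bf)), m$boundary_sets$csf_outer)
  # five named sulcal pockets, disjoint, all CSF
  expect_named(m$sulci, c("sylvian", "superior_temporal", "central",
                          "intra_parietal", "superior_frontal"))
  all_pockets <- unlist(m$sulci)
  expect_identical(anyDuplicated(all_pockets), 0L)
  expect_true(all(m$region[all_pockets] == match("CSF", region_labels())))
})

test_that("infeasible geometries are rejected with descriptive errors", {
  expect_error(phantom_params(fold_gap = 0), "fold_gap")
  expect_error(phantom_params(n_folds = 9, fold_amplitude = 20), "folds")
  expect_error(phantom_params(ventricle_semiaxes = c(40, 30)), "infeasible")
  expect_error(phantom_params(dimension = 4), "dimension")
  expect_error(phantom_params(csf_smoothing = 10), "csf_smoothing")
  # hippocampus not adjacent to the ventricle
  expect_error(build_brain_phantom(
    phantom_params(hippocampus_center = c(0, -38), hippocampus_radius = 4)),
    "hippocampus")
})

test_that("region boundary extraction: circle length, fold count, error cases", {
  dsk <- mesh_disk(20, 2)
  loops <- extract_region_boundary(dsk, "GM")
  expect_length(loops, 1L)
  expect_lt(abs(loops[[1]]$length - 2 * pi * 20) / (2 * pi * 20), 0.01)
  # outer WM-core contour of a folded phantom oscillates n_folds times
  m <- study_phantom()
  wb <- extract_region_boundary(m, c("WM", "HIPPO", "VENT"))
  co <- wb[[1]]$coords
  rad <- sqrt(rowSums(co^2))
  sgn <- sign(rad - mean(rad))
  sgn <- sgn[sgn != 0]
  n_changes <- sum(diff(c(sgn, sgn[1])) != 0)
  expect_identical(n_changes, 2L * 5L)  # one up + one down crossing per fold
  expect_error(extract_region_boundary(dsk, "VENT"), "no elements")
  expect_error(extract_region_boundary(dsk, "nonsense"), "unknown region")
})

test_that("pial surface is simple and the hippocampus touches the ventricle", {
  m <- study_phantom()
  pial <- extract_region_boundary(m, tissue_labels())
  expect_false(atrophysim:::polyline_self_intersects(pial[[1]]$coords))
  vent_nodes <- unique(as.vector(m$elements[m$region == match("VENT", region_labels()), ]))
  hip_nodes <- unique(as.vector(m$elements[m$region == match("HIPPO", region_labels()), ]))
  expect_gt(length(intersect(hip_nodes, vent_nodes)), 0L)
})

test_that("quality report flags inverted elements", {
  m <- mesh_disk(10, 3)
  m$elements[1, ] <- m$elements[1, c(1, 3, 2)]  # invert one triangle
  q <- mesh_quality_report(m)
  expect_identical(q$n_inverted, 1L)
  expect_lt(q$min_measure, 0)
  q2 <- mesh_quality_report(mesh_disk(10, 3), edge_band = c(2, 2.3))
  expect_true(q2$n_edges_outside_band >= 0)
})

test_that("3D extrusion is conforming with positive volumes and full exterior anchor", {
  m3 <- build_brain_phantom(phantom_params(target_edge_length = 6, dimension = 3,
                                           slab_layers = 2))
  expect_identical(m3$dim, 3L)
  expect_true(all(element_measures(m3) > 0))
  expect_setequal(unique(m3$region), 1:5)
  # conforming: every interior facet is shared by exactly two tets
  el <- m3$elements
  facets <- rbind(el[, -1], el[, -2], el[, -3], el[, -4])
  key <- apply(facets, 1, function(r) paste(sort(r), collapse = "-"))
  cnt <- table(table(key))
  expect_true(all(names(cnt) %in% c("1", "2")))
  bf <- atrophysim:::subset_boundary_facets(m3, seq_len(nrow(el)))
  expect_setequal(unique(as.vector(bf)), m3$boundary_sets$csf_outer)
  # measure bookkeeping survives extrusion
  v <- region_measures(m3)
  expect_lt(abs(sum(v) - attr(v, "total")) / attr(v, "total"), 1e-10)
})
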