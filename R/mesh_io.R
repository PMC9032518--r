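# Mesh and field I/O: ASCII VTK unstructured grids (.vtu), a Gmsh 4.1
# ASCII subset (.msh), and .pvd time-series collections. Region labels are
# written as integer cell data plus a JSON sidecar name table
# (<file>.labels.json) carrying region and sulcus names.

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

labels_sidecar_path <- function(path) paste0(path, ".labels.json")

write_labels_sidecar <- function(mesh, path) {
  sidecar <- list(
    region_names = as.list(setNames(seq_along(mesh$region_names), mesh$region_names)),
    sulci = lapply(mesh$sulci, function(ix) as.integer(ix)),
    boundary_sets = lapply(mesh$boundary_sets, function(ix) as.integer(ix)),
    target_edge = mesh$target_edge
  )
  jsonlite::write_json(sidecar, labels_sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

read_labels_sidecar <- function(path) {
  sp <- labels_sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write a mesh (with optional fields) as ASCII VTK `.vtu`
#'
#' Nodal fields go to PointData, per-element fields to CellData; the region
#' label is always written as integer cell data `"region"`. A JSON sidecar
#' `<path>.labels.json` stores the region name table, sulcus element sets
#' and boundary node sets.
#'
#' @param mesh a [labeled_mesh].
#' @param path output file path (conventionally `.vtu`).
#' @param point_data named list of numeric vectors (length = node count) or
#'   matrices (node count x components).
#' @param cell_data named list of numeric vectors (length = element count).
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  pts <- cbind(mesh$nodes, matrix(0, n, 3 - mesh$dim))
  vtk_type <- if (mesh$dim == 2L) 5L else 10L
  da <- function(name, x, comps = 1L, type = "Float64") {
    vals <- if (is.matrix(x)) t(x) else x
    sprintf('<DataArray type="%s" Name="%s" NumberOfComponents="%d" format="ascii">\n%s\n</DataArray>',
            type, name, comps, paste(fmt_num(as.vector(vals)), collapse = " "))
  }
  cd <- c(list(sprintf('<DataArray type="Int32" Name="region" NumberOfComponents="1" format="ascii">\n%s\n</DataArray>',
                       paste(mesh$region, collapse = " "))),
          lapply(names(cell_data), function(nm) da(nm, cell_data[[nm]])))
  pd <- lapply(names(point_data), function(nm) {
    x <- point_data[[nm]]
    if (is.matrix(x) && ncol(x) == mesh$dim) x <- cbind(x, matrix(0, nrow(x), 3 - mesh$dim))
    da(nm, x, if (is.matrix(x)) ncol(x) else 1L)
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    '<UnstructuredGrid>',
    sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m),
    '<Points>',
    sprintf('<DataArray type="Float64" NumberOfComponents="3" format="ascii">\n%s\n</DataArray>',
            paste(fmt_num(as.vector(t(pts))), collapse = " ")),
    '</Points>',
    '<Cells>',
    sprintf('<DataArray type="Int32" Name="connectivity" format="ascii">\n%s\n</DataArray>',
            paste(as.vector(t(mesh$elements)) - 1L, collapse = " ")),
    sprintf('<DataArray type="Int32" Name="offsets" format="ascii">\n%s\n</DataArray>',
            paste(seq_len(m) * (mesh$dim + 1L), collapse = " ")),
    sprintf('<DataArray type="Int32" Name="types" format="ascii">\n%s\n</DataArray>',
            paste(rep(vtk_type, m), collapse = " ")),
    '</Cells>',
    '<PointData>', unlist(pd), '</PointData>',
    '<CellData>', unlist(cd), '</CellData>',
    '</Piece>', '</UnstructuredGrid>', '</VTKFile>'
  ), con)
  write_labels_sidecar(mesh, path)
  invisible(path)
}

#' Read an ASCII `.vtu` written by this package (or compatible)
#'
#' Understands ASCII UnstructuredGrid files with triangle (type 5) or
#' tetrahedron (type 10) cells and an integer `"region"` cell array. If a
#' `<path>.labels.json` sidecar is present, sulci and boundary sets are
#' restored.
#'
#' @param path file path.
#' @return A [labeled_mesh].
#' @export
read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  numtext <- function(node) as.numeric(strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]])
  pts <- numtext(xml2::xml_find_first(piece, ".//Points/DataArray"))
  pts <- matrix(pts, ncol = 3, byrow = TRUE)
  conn <- numtext(xml2::xml_find_first(piece, './/Cells/DataArray[@Name="connectivity"]'))
  types <- numtext(xml2::xml_find_first(piece, './/Cells/DataArray[@Name="types"]'))
  vt <- unique(types)
  if (length(vt) != 1L || !vt %in% c(5, 10))
    stop_atrophy("read_vtu: only homogeneous triangle/tetrahedron meshes are supported")
  d1 <- if (vt == 5) 3L else 4L
  el <- matrix(as.integer(conn) + 1L, ncol = d1, byrow = TRUE)
  reg_node <- xml2::xml_find_first(piece, './/CellData/DataArray[@Name="region"]')
  if (is.na(xml2::xml_name(reg_node)))
    stop_atrophy("read_vtu: no 'region' cell data found in %s", path)
  region <- as.integer(numtext(reg_node))
  dim <- if (vt == 5) 2L else 3L
  side <- read_labels_sidecar(path)
  bset <- list(); sulci <- list(); te <- NA_real_
  if (!is.null(side)) {
    bset <- lapply(side$boundary_sets, as.integer)
    sulci <- lapply(side$sulci, as.integer)
    te <- side$target_edge %||% NA_real_
  }
  labeled_mesh(pts[, seq_len(dim), drop = FALSE], el, region,
               boundary_sets = bset, sulci = sulci, target_edge = te)
}

#' Write a mesh in Gmsh 4.1 ASCII format
#'
#' One discrete surface (2D) or volume (3D) entity per region; region names
#' go to `$PhysicalNames` and the same JSON sidecar as [write_vtu] is
#' written for sulci and boundary sets.
#'
#' @param mesh a [labeled_mesh].
#' @param path output path (conventionally `.msh`).
#' @return `path`, invisibly.
#' @export
write_msh <- function(mesh, path) {
  dim <- mesh$dim
  n <- nrow(mesh$nodes)
  regions_present <- sort(unique(mesh$region))
  con <- file(path, "w")
  on.exit(close(con))
  out <- c("$MeshFormat", "4.1 0 8", "$EndMeshFormat", "$PhysicalNames",
           sprintf("%d", length(regions_present)),
           sprintf('%d %d "%s"', dim, regions_present, mesh$region_names[regions_present]),
           "$EndPhysicalNames", "$Entities")
  ent_counts <- c(0L, 0L, 0L, 0L)
  ent_counts[dim + 1L] <- length(regions_present)
  out <- c(out, paste(ent_counts, collapse = " "))
  bb <- apply(mesh$nodes, 2, range)
  bbox <- c(bb[1, ], rep(0, 3 - dim), bb[2, ], rep(0, 3 - dim))
  out <- c(out, sprintf("%d %s 1 %d", regions_present,
                        paste(fmt_num(bbox), collapse = " "), regions_present),
           "$EndEntities", "$Nodes",
           sprintf("1 %d 1 %d", n, n),
           sprintf("%d %d 0 %d", dim, regions_present[1], n),
           as.character(seq_len(n)),
           apply(cbind(mesh$nodes, matrix(0, n, 3 - dim)), 1,
                 function(r) paste(fmt_num(r), collapse = " ")),
           "$EndNodes", "$Elements")
  etype <- if (dim == 2L) 2L else 4L
  blocks <- character(0)
  tag0 <- 0L
  for (r in regions_present) {
    ix <- which(mesh$region == r)
    blocks <- c(blocks, sprintf("%d %d %d %d", dim, r, etype, length(ix)),
                paste(tag0 + seq_along(ix),
                      apply(mesh$elements[ix, , drop = FALSE], 1, paste, collapse = " ")))
    tag0 <- tag0 + length(ix)
  }
  out <- c(out, sprintf("%d %d 1 %d", length(regions_present), nrow(mesh$elements),
                        nrow(mesh$elements)),
           blocks, "$EndElements")
  writeLines(out, con)
  write_labels_sidecar(mesh, path)
  invisible(path)
}

#' Read the Gmsh 4.1 ASCII subset written by [write_msh]
#'
#' @param path file path.
#' @return A [labeled_mesh].
#' @export
read_msh <- function(path) {
  ln <- readLines(path)
  sect <- function(name) {
    i0 <- which(ln == paste0("$", name)); i1 <- which(ln == paste0("$End", name))
    if (!length(i0) || !length(i1)) stop_atrophy("read_msh: missing $%s section", name)
    ln[(i0 + 1L):(i1 - 1L)]
  }
  nodes_s <- sect("Nodes")
  hdr <- as.numeric(strsplit(nodes_s[1], "\\s+")[[1]])
  n_blocks <- hdr[1]; n_nodes <- hdr[2]
  coords <- matrix(NA_real_, n_nodes, 3)
  pos <- 2L
  for (b in seq_len(n_blocks)) {
    bh <- as.numeric(strsplit(nodes_s[pos], "\\s+")[[1]])
    nb <- bh[4]
    tags <- as.integer(nodes_s[pos + seq_len(nb)])
    xyz <- do.call(rbind, lapply(nodes_s[pos + nb + seq_len(nb)],
                                 function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
    coords[tags, ] <- xyz[, 1:3]
    pos <- pos + 2L * nb + 1L
  }
  el_s <- sect("Elements")
  hdr <- as.numeric(strsplit(el_s[1], "\\s+")[[1]])
  n_blocks <- hdr[1]
  els <- list(); regs <- list()
  pos <- 2L
  dim <- 2L
  for (b in seq_len(n_blocks)) {
    bh <- as.numeric(strsplit(el_s[pos], "\\s+")[[1]])
    ent_dim <- bh[1]; ent_tag <- bh[2]; etype <- bh[3]; nb <- bh[4]
    d1 <- if (etype == 2) 3L else if (etype == 4) 4L else
      stop_atrophy("read_msh: unsupported element type %d", etype)
    dim <- if (etype == 2) 2L else 3L
    rows <- do.call(rbind, lapply(el_s[pos + seq_len(nb)],
                                  function(s) as.integer(strsplit(trimws(s), "\\s+")[[1]])))
    els[[b]] <- rows[, 1L + seq_len(d1), drop = FALSE]
    regs[[b]] <- rep(ent_tag, nb)
    pos <- pos + nb + 1L
  }
  el <- do.call(rbind, els)
  region <- as.integer(do.call(c, regs))
  side <- read_labels_sidecar(path)
  bset <- list(); sulci <- list(); te <- NA_real_
  if (!is.null(side)) {
    bset <- lapply(side$boundary_sets, as.integer)
    sulci <- lapply(side$sulci, as.integer)
    te <- side$target_edge %||% NA_real_
  }
  labeled_mesh(coords[, seq_len(dim), drop = FALSE], el, region,
               boundary_sets = bset, sulci = sulci, target_edge = te)
}

#' Write a `.pvd` collection referencing a `.vtu` time series
#'
#' @param path output `.pvd` path.
#' @param times numeric vector of time stamps (years).
#' @param files character vector of `.vtu` file names (relative to the pvd).
#' @return `path`, invisibly.
#' @export
write_pvd <- function(path, times, files) {
  stopifnot(length(times) == length(files))
  writeLines(c(
    '<?xml version="1.0"?>',
    '<VTKFile type="Collection" version="0.1" byte_order="LittleEndian">',
    '<Collection>',
    sprintf('<DataSet timestep="%s" group="" part="0" file="%s"/>', fmt_num(times), files),
    '</Collection>', '</VTKFile>'), path)
  invisible(path)
}
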