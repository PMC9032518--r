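# Run configuration: YAML round-trip, validation with key-level error
# messages, and the all-in-one pipeline (phantom -> healthy run -> AD run
# -> comparative morphometry) with a reproducibility manifest.

config_sections <- c("phantom", "materials", "spreading", "simulation", "output")

#' Default run configuration
#'
#' Defaults reproduce the reference setup: the standard material table,
#' hippocampal seeding at c0 = 0.3, a 40-year span at dt = 0.1 yr, and the
#' zero-displacement anchor on the outer CSF surface.
#'
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function() {
  pp <- phantom_params()
  mat <- default_materials()
  structure(list(
    phantom = unclass(pp),
    materials = lapply(rownames(mat), function(r) as.list(mat[r, ])) |>
      setNames(rownames(mat)),
    spreading = list(c0_seed = 0.3, seed_region = "HIPPO"),
    simulation = list(t_end = 40, dt = 0.1, modes = c("healthy", "ad"),
                      newton_tol = 1e-8, newton_max_iter = 50,
                      dirichlet = "csf_outer", output_every = 40,
                      beta = 50, theta_floor = 0.5, seed = 1L),
    output = list(dir = "results", write_vtu = FALSE, write_msh = FALSE)
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' Checks section and key names (unknown keys are rejected), rebuilds the
#' phantom parameters and material table through their validating
#' constructors, and checks simulation invariants. Errors name the
#' offending key (e.g. `simulation.dt`).
#'
#' @param cfg a list as produced by [default_run_config] or [load_config].
#' @return The validated `run_config`, invisibly.
#' @export
validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), config_sections)
  if (length(unknown))
    stop_atrophy("unknown config section(s): %s", paste(unknown, collapse = ", "))
  def <- default_run_config()
  for (sec in c("phantom", "spreading", "simulation", "output")) {
    bad <- setdiff(names(cfg[[sec]]), names(def[[sec]]))
    if (length(bad))
      stop_atrophy("unknown config key(s): %s",
                   paste(paste0(sec, ".", bad), collapse = ", "))
  }
  do.call(phantom_params, cfg$phantom)   # validates geometry
  run_config_materials(cfg)              # validates the material table
  sim <- cfg$simulation
  if (!is.numeric(sim$dt) || sim$dt <= 0) stop_atrophy("simulation.dt must be > 0")
  if (!is.numeric(sim$t_end) || sim$t_end < 0) stop_atrophy("simulation.t_end must be >= 0")
  if (sim$t_end > 0 && sim$dt > sim$t_end) stop_atrophy("simulation.dt must not exceed simulation.t_end")
  if (!all(sim$modes %in% c("healthy", "ad")))
    stop_atrophy("simulation.modes must be a subset of {healthy, ad}")
  if (sim$newton_tol <= 0) stop_atrophy("simulation.newton_tol must be > 0")
  sp <- cfg$spreading
  if (sp$c0_seed < 0 || sp$c0_seed > 1) stop_atrophy("spreading.c0_seed must lie in [0, 1]")
  invisible(structure(cfg, class = "run_config"))
}

run_config_materials <- function(cfg) {
  rows <- cfg$materials
  miss <- setdiff(region_labels(), names(rows))
  if (length(miss))
    stop_atrophy("materials: missing region(s): %s", paste(miss, collapse = ", "))
  df <- do.call(rbind, lapply(region_labels(), function(r) {
    x <- rows[[r]]
    data.frame(lambda = x$lambda, mu = x$mu,
               G_h = x$G_h %||% NA_real_, G_c = x$G_c %||% NA_real_,
               c_crit = x$c_crit %||% NA_real_, d = x$d, alpha = x$alpha)
  }))
  rownames(df) <- region_labels()
  material_table(df)
}

#' Load and validate a YAML run configuration
#'
#' Missing sections/keys fall back to the defaults of
#' [default_run_config]; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_atrophy("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  def <- default_run_config()
  unknown <- setdiff(names(raw), config_sections)
  if (length(unknown))
    stop_atrophy("unknown config section(s): %s", paste(unknown, collapse = ", "))
  cfg <- def
  for (sec in intersect(names(raw), config_sections)) {
    if (sec == "materials") {
      for (r in names(raw$materials))
        cfg$materials[[r]] <- utils::modifyList(cfg$materials[[r]],
                                                raw$materials[[r]])
    } else {
      bad <- setdiff(names(raw[[sec]]), names(def[[sec]]))
      if (length(bad))
        stop_atrophy("unknown config key(s): %s",
                     paste(paste0(sec, ".", bad), collapse = ", "))
      cfg[[sec]] <- utils::modifyList(cfg[[sec]], raw[[sec]])
    }
  }
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

#' Save a run configuration as YAML
#'
#' Round-trips losslessly through [load_config].
#'
#' @param cfg a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Phantom generation, one simulation per requested mode, per-mode
#' morphometry reports, a comparative summary (AD vs healthy orderings)
#' when both modes run, and a manifest with MD5 checksums of every
#' artifact, the config, package version and seeds.
#'
#' @param cfg a `run_config` (validated here).
#' @param out_dir output directory (overrides `cfg$output$dir`); created
#'   if missing.
#' @param quiet suppress progress messages.
#' @return List with `mesh`, per-mode `results` and `reports`, and
#'   `manifest` (also written as `manifest.json`).
#' @export
run_pipeline <- function(cfg = default_run_config(), out_dir = NULL,
                         quiet = TRUE) {
  validate_run_config(cfg)
  out_dir <- out_dir %||% cfg$output$dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  pp <- do.call(phantom_params, cfg$phantom)
  mat <- run_config_materials(cfg)
  set.seed(cfg$simulation$seed)
  mesh <- tryCatch(build_brain_phantom(pp),
                   error = function(e) stop_atrophy("pipeline stage 'phantom': %s",
                                                    conditionMessage(e)))
  files <- character(0)
  mesh_path <- file.path(out_dir, "phantom.vtu")
  write_vtu(mesh, mesh_path)
  files <- c(files, mesh_path, labels_sidecar_path(mesh_path))
  if (isTRUE(cfg$output$write_msh)) {
    mp <- file.path(out_dir, "phantom.msh")
    write_msh(mesh, mp)
    files <- c(files, mp, labels_sidecar_path(mp))
  }
  sp <- spreading_params(mat, c0_seed = cfg$spreading$c0_seed,
                         seed_region = cfg$spreading$seed_region)
  results <- list(); reports <- list()
  for (mode in cfg$simulation$modes) {
    sc <- simulation_config(
      t_end = cfg$simulation$t_end, dt = cfg$simulation$dt, mode = mode,
      newton_tol = cfg$simulation$newton_tol,
      newton_max_iter = cfg$simulation$newton_max_iter,
      dirichlet = cfg$simulation$dirichlet,
      output_every = cfg$simulation$output_every,
      beta = cfg$simulation$beta, theta_floor = cfg$simulation$theta_floor,
      seed = cfg$simulation$seed)
    res <- tryCatch(run_simulation(mesh, mat, sc, spreading = sp, quiet = quiet),
                    error = function(e) stop_atrophy("pipeline stage 'simulate[%s]': %s",
                                                     mode, conditionMessage(e)))
    results[[mode]] <- res
    # volume ledger CSV
    led <- file.path(out_dir, sprintf("volumes_%s.csv", mode))
    utils::write.csv(region_volume_series(res), led, row.names = FALSE)
    files <- c(files, led)
    rep <- tryCatch(build_report(res),
                    error = function(e) stop_atrophy("pipeline stage 'morphometry[%s]': %s",
                                                     mode, conditionMessage(e)))
    reports[[mode]] <- rep
    files <- c(files, write_report(rep, out_dir))
    if (isTRUE(cfg$output$write_vtu)) {
      vfiles <- character(0)
      for (si in seq_along(res$snapshots)) {
        sn <- res$snapshots[[si]]
        vp <- file.path(out_dir, sprintf("%s_%03d.vtu", mode, si - 1L))
        pd <- list(displacement = sn$u)
        if (!is.null(sn$c)) pd$concentration <- sn$c
        write_vtu(mesh, vp, point_data = pd, cell_data = list(theta = sn$theta))
        vfiles <- c(vfiles, vp)
      }
      pvd <- file.path(out_dir, sprintf("%s.pvd", mode))
      write_pvd(pvd, vapply(res$snapshots, `[[`, numeric(1), "time"),
                basename(vfiles))
      files <- c(files, vfiles, pvd)
    }
  }
  comparison <- NULL
  if (all(c("healthy", "ad") %in% names(results))) {
    h <- results$healthy; a <- results$ad
    comparison <- list(
      vent_ad_ge_healthy_all_times = all(a$volumes[, "VENT"] >= h$volumes[, "VENT"] - 1e-9),
      tissue_ad_le_healthy_all_times =
        all(rowSums(a$volumes[, tissue_labels()]) <=
              rowSums(h$volumes[, tissue_labels()]) + 1e-9),
      hippocampal_fraction_change_ad_pct =
        reports$ad$hippocampal_fraction_change_pct[["intracranial"]],
      hippocampal_fraction_change_healthy_pct =
        reports$healthy$hippocampal_fraction_change_pct[["intracranial"]],
      gi_young = reports$healthy$gi$young$mean,
      gi_aged_healthy = reports$healthy$gi$aged$mean,
      gi_aged_ad = reports$ad$gi$aged$mean,
      min_theta_ad = min(a$theta_final),
      min_theta_healthy = min(h$theta_final)
    )
    cp <- file.path(out_dir, "comparison.json")
    jsonlite::write_json(comparison, cp, auto_unbox = TRUE, digits = NA)
    files <- c(files, cp)
  }
  cfg_path <- file.path(out_dir, "config_used.yaml")
  save_config(cfg, cfg_path)
  files <- c(files, cfg_path)
  manifest <- list(
    package = "atrophysim",
    version = as.character(utils::packageVersion("atrophysim")),
    seed = cfg$simulation$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    files = lapply(setNames(nm = basename(files)), function(f) {
      p <- file.path(out_dir, f)
      list(md5 = unname(tools::md5sum(p)), bytes = file.size(p))
    })
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(list(mesh = mesh, results = results, reports = reports,
                 comparison = comparison, manifest = manifest,
                 files = c(files, mp)))
}
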