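#' Material and spreading parameter table
#'
#' Per-region constitutive and biomarker parameters: Lame constants
#' `lambda`, `mu` (kPa), healthy and concentration-driven atrophy rates
#' `G_h`, `G_c` (1/year, NA for non-atrophying fluid regions), critical
#' biomarker concentration `c_crit`, biomarker diffusivity `d` (mm^2/year)
#' and logistic growth rate `alpha` (1/year).
#'
#' @param df data frame with one row per region (row names from
#'   [region_labels()]) and the columns above.
#' @return A `material_table` (data frame subclass).
#' @export
material_table <- function(df) {
  need <- c("lambda", "mu", "G_h", "G_c", "c_crit", "d", "alpha")
  if (!all(need %in% names(df)))
    stop_atrophy("material table must have columns: %s", paste(need, collapse = ", "))
  miss <- setdiff(region_labels(), rownames(df))
  if (length(miss))
    stop_atrophy("material table is missing region(s): %s", paste(miss, collapse = ", "))
  df <- df[region_labels(), need]
  if (any(df$mu <= 0) || any(df$lambda <= 0))
    stop_atrophy("Lame constants mu and lambda must be > 0 for every region")
  if (any(!is.na(df$G_h) & df$G_h < 0) || any(!is.na(df$G_c) & df$G_c < 0))
    stop_atrophy("atrophy rates G_h, G_c must be >= 0 where defined")
  cc <- df$c_crit[!is.na(df$c_crit)]
  if (any(cc <= 0 | cc >= 1)) stop_atrophy("c_crit must lie in (0, 1) where defined")
  if (any(df$d < 0)) stop_atrophy("diffusivity d must be >= 0")
  if (any(df$alpha < 0)) stop_atrophy("growth rate alpha must be >= 0")
  class(df) <- c("material_table", "data.frame")
  df
}

#' Default material table
#'
#' White and gray matter carry stiffness, atrophy rates and spreading
#' parameters; the hippocampus shares gray-matter values; ventricles and
#' CSF are non-atrophying, non-diffusing elastic regions. Units: kPa,
#' 1/year, mm^2/year.
#'
#' @return A [material_table].
#' @export
default_materials <- function() {
  material_table(data.frame(
    row.names = c("WM", "GM", "HIPPO", "VENT", "CSF"),
    lambda = c(64.67, 32.33, 32.33, 29.77, 7.22),
    mu     = c(2,     1,     1,     15.34, 14.43),
    G_h    = c(0.0015, 0.001, 0.001, NA,   NA),
    G_c    = c(0.0035, 0.002, 0.002, NA,   NA),
    c_crit = c(0.5,   0.5,   0.5,   NA,   NA),
    d      = c(15,    15,    15,    0,    0),
    alpha  = c(0.09,  0.09,  0.09,  0.09, 0.09)
  ))
}

#' Alternative preset: ultrasoft fluid regions
#'
#' Same tissue parameters as [default_materials()] but with ventricles and
#' CSF two orders of magnitude softer than gray matter, for exploring the
#' "brain suspended in an ultrasoft, highly compressible fluid proxy"
#' regime. Not the default.
#'
#' @return A [material_table].
#' @export
materials_ultrasoft_csf <- function() {
  m <- default_materials()
  m["VENT", c("lambda", "mu")] <- c(0.05, 0.01)
  m["CSF", c("lambda", "mu")] <- c(0.05, 0.01)
  m
}

# per-element parameter lookup helpers
mat_param <- function(mat, region_idx, col) {
  mat[[col]][region_idx]
}
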