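#' @importFrom stats approx median sd setNames
#' @importFrom utils write.csv modifyList head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_atrophy <- function(...) stop(sprintf(...), call. = FALSE)

#' Canonical region labels
#'
#' The five anatomical regions every labeled mesh carries: white matter,
#' gray matter, hippocampus, ventricles, and cerebrospinal fluid.
#'
#' @return Character vector of the five region labels, in canonical order.
#' @export
region_labels <- function() c("WM", "GM", "HIPPO", "VENT", "CSF")

#' Tissue region labels
#'
#' Regions that undergo atrophy and count as brain tissue for volume
#' fractions and the pial/tissue boundary (everything except CSF).
#'
#' @return Character vector of labels.
#' @export
tissue_labels <- function() c("WM", "GM", "HIPPO", "VENT")

# row-wise euclidean norm
row_norms <- function(m) sqrt(rowSums(m * m))

# polygon signed area (x, y vectors, closed implicitly)
polygon_signed_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  0.5 * sum(x[j] * y - x * y[j])
}

# polygon perimeter (closed implicitly)
polygon_perimeter <- function(x, y) {
  n <- length(x)
  j <- c(seq_len(n)[-1L], 1L)
  sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
}
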