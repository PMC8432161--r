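# Surface-based Gaussian smoothing of per-vertex overlays.
#
# Distances are Dijkstra shortest edge-paths (see geodesic_distances). The
# Gaussian kernel K_ij = exp(-d_ij^2 / (2 sigma^2)), truncated at 3 sigma,
# is balanced with respect to the vertex-area measure (Sinkhorn scaling of
# the symmetric kernel) so that the smoothing operator both preserves
# constants exactly and conserves the area-weighted sum of any overlay.

fwhm_to_sigma <- function(fwhm_mm) fwhm_mm / (2 * sqrt(2 * log(2)))

#' Precompute a smoothing operator for a mesh
#'
#' Returns a sparse row-stochastic matrix `W` with the additional property
#' `t(a) %*% W == t(a)` for the vertex-area vector `a`, so `W %*% x`
#' preserves constants and conserves area-weighted mass. Compute once per
#' (mesh, fwhm) and reuse across overlays and subjects sharing the mesh.
#'
#' @param surface a [hemi_surface()].
#' @param fwhm_mm kernel full width at half maximum in mm (> 0).
#' @param distances optional precomputed geodesic distance matrix.
#' @return sparse `dgCMatrix` smoothing operator.
#' @export
smoothing_weights <- function(surface, fwhm_mm, distances = NULL) {
  stopifnot(fwhm_mm > 0)
  sigma <- fwhm_to_sigma(fwhm_mm)
  if (is.null(distances)) distances <- geodesic_distances(surface)
  nv <- n_vertices(surface)
  keep <- which(distances <= 3 * sigma)  # includes the diagonal (d = 0)
  ij <- arrayInd(keep, dim(distances))
  k <- Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2],
                            x = exp(-distances[keep]^2 / (2 * sigma^2)),
                            dims = c(nv, nv))
  a <- overlay_values(suppressWarnings(vertex_areas(surface)))
  # symmetric Sinkhorn: find u with u_i * sum_j K_ij u_j a_j = 1
  u <- rep(1, nv)
  for (iter in 1:200) {
    f <- as.numeric(k %*% (u * a))
    if (max(abs(u * f - 1)) < 1e-12) break
    u <- sqrt(u / f)
  }
  w <- Matrix::Diagonal(x = u) %*% k %*% Matrix::Diagonal(x = u * a)
  methods::as(w, "CsparseMatrix")
}

#' Smooth an overlay on a surface with a geodesic Gaussian kernel
#'
#' `fwhm_mm = 0` is the identity. `NA` (masked) vertices are excluded from
#' the kernel support and remain `NA` in the output; smoothing then
#' renormalizes over the unmasked neighbourhood.
#'
#' @param surface a [hemi_surface()].
#' @param x an [overlay()] or numeric vector.
#' @param fwhm_mm kernel FWHM in mm (>= 0).
#' @param weights optional operator from [smoothing_weights()] (must match
#'   `fwhm_mm`'s kernel if supplied).
#' @return smoothed [overlay()].
#' @export
smooth_overlay <- function(surface, x, fwhm_mm, weights = NULL) {
  vals <- overlay_values(x)
  check_overlay_length(vals, surface)
  if (fwhm_mm == 0)
    return(overlay(vals, name = attr(x, "name") %||% "overlay"))
  if (is.null(weights)) weights <- smoothing_weights(surface, fwhm_mm)
  masked <- is.na(vals)
  if (any(masked)) {
    v0 <- ifelse(masked, 0, vals)
    num <- as.numeric(weights %*% v0)
    den <- as.numeric(weights %*% as.numeric(!masked))
    out <- ifelse(masked | den == 0, NA_real_, num / den)
  } else {
    out <- as.numeric(weights %*% vals)
  }
  overlay(out, name = attr(x, "name") %||% "overlay",
          units = attr(x, "units") %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
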