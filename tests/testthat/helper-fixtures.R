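# Shared fixtures, all built in code at test time.

# regular icosahedron with unit edge length
unit_icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)) / 2
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  hemi_surface(v, f, "left", "mid", check = FALSE)
}

# planar grid, alternating diagonal orientation (isotropic triangulation)
grid_surface <- function(nx, ny, spacing = 1) {
  vid <- function(i, j) (j - 1L) * nx + i
  v <- cbind(rep(seq_len(nx), ny), rep(seq_len(ny), each = nx), 0) *
    spacing
  tri <- vector("list", 2L * (nx - 1L) * (ny - 1L))
  k <- 0L
  for (j in seq_len(ny - 1L)) for (i in seq_len(nx - 1L)) {
    a <- vid(i, j); b <- vid(i + 1L, j)
    cc <- vid(i, j + 1L); d <- vid(i + 1L, j + 1L)
    if ((i + j) %% 2L == 0L) {
      tri[[k + 1L]] <- c(a, b, d); tri[[k + 2L]] <- c(a, d, cc)
    } else {
      tri[[k + 1L]] <- c(a, b, cc); tri[[k + 2L]] <- c(b, d, cc)
    }
    k <- k + 2L
  }
  hemi_surface(v, do.call(rbind, tri), "left", "mid", check = FALSE)
}

scaled_icosphere <- function(subdivision, radius = 1, hemisphere = "left") {
  ico <- icosphere(subdivision)
  hemi_surface(ico$vertices * radius, ico$triangles, hemisphere, "mid",
               check = FALSE)
}

# the "stated world" cohort used by the acceptance criteria: 8 patients,
# 10 controls, subdivision-4 meshes, 3-sd effects; memoized so multiple
# test files can share one computation
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_world <- function() {
  if (is.null(.acceptance_cache$world)) {
    cohort <- generate_cohort(synthetic_cohort_spec(), seed = 42L)
    prepared <- prepare_cohort_features(cohort)
    .acceptance_cache$world <- list(cohort = cohort, prepared = prepared)
  }
  .acceptance_cache$world
}

# independent Sinkhorn-balanced Gaussian smoother from exact distances
exact_smoother <- function(distances, areas, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  k <- exp(-distances^2 / (2 * sigma^2))
  k[distances > 3 * sigma] <- 0
  u <- rep(1, nrow(k))
  for (it in 1:500) {
    f <- as.numeric(k %*% (u * areas))
    if (max(abs(u * f - 1)) < 1e-12) break
    u <- sqrt(u / f)
  }
  diag(u) %*% k %*% diag(u * areas)
}

# brute-force flood fill over a vertex subset (clustering oracle)
flood_fill_components <- function(surface, keep) {
  ed <- lesionplan:::mesh_edges(surface)$edges
  nbr <- split(c(ed[, 2], ed[, 1]), c(ed[, 1], ed[, 2]))
  seen <- logical(nrow(surface$vertices))
  comps <- list()
  for (v0 in keep) {
    if (seen[v0]) next
    queue <- v0; seen[v0] <- TRUE; comp <- integer()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in nbr[[as.character(v)]] %||% integer())
        if (w %in% keep && !seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tmp_cohort_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE)
  path
}
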