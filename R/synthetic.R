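# Fully synthetic cohorts: vertex-paired mirror hemispheres built from
# deformed icospheres, smooth control feature fields with Gaussian noise,
# geodesic lesion patches with a tapered-cosine edge, and linear electrode
# trajectories with labelled contacts. Everything is deterministic from a
# seed, so the whole pipeline is testable without imaging data.
#
# Synthetic meshes are spheres, not folded cortices: sulcal depth, mean
# curvature and intrinsic curvature are generated as smooth fields rather
# than recomputed from geometry, because the classifier consumes channels,
# not geometry.

#' Unit icosphere mesh
#'
#' Icosahedron subdivided `subdivision` times, vertices projected to the
#' unit sphere; vertex count is `10 * 4^subdivision + 2`.
#'
#' @param subdivision number of 4-to-1 triangle subdivisions (>= 0).
#' @return list with `vertices` (n x 3, unit norm) and `triangles`.
#' @export
icosphere <- function(subdivision = 4) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivision)) {
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mids <- new.env()
    newv <- list()
    midpoint <- function(a, b) {
      k <- edge_key(a, b)
      id <- mids[[k]]
      if (is.null(id)) {
        m <- (v[a, ] + v[b, ]) / 2
        m <- m / sqrt(sum(m^2))
        newv[[length(newv) + 1L]] <<- m
        id <- nrow(v) + length(newv)
        mids[[k]] <- id
      }
      id
    }
    nf <- matrix(0L, 4 * nrow(f), 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[4 * i - 3, ] <- c(a, ab, ca)
      nf[4 * i - 2, ] <- c(b, bc, ab)
      nf[4 * i - 1, ] <- c(cc, ca, bc)
      nf[4 * i, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  list(vertices = v, triangles = f)
}

# deterministic smooth scalar field on the unit sphere, even in x so the
# mirrored hemispheres carry identical mean fields
smooth_sphere_field <- function(u, which = 1L) {
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  switch(((which - 1L) %% 4L) + 1L,
         y,
         y * z,
         z + 0.5 * x^2,
         0.5 * (y^2 - z^2) + y * z * 0.5)
}

#' Build a vertex-paired pair of synthetic hemispheres
#'
#' Two mirror-symmetric deformed icospheres (left at negative x), each
#' with white, gray and mid-thickness surfaces; the gray surface is the
#' white surface offset outward along the radial direction by a smooth
#' thickness field. Template correspondence between hemispheres is the
#' identity (vertex i on the left corresponds to vertex i on the right).
#'
#' @param subdivision icosphere subdivision level (>= 2).
#' @param radius hemisphere radius in mm (default 50, giving a surface
#'   area of roughly a third of a real hemisphere's).
#' @param center_offset_mm distance of each hemisphere center from the
#'   midline (default 32).
#' @param thickness_base_mm mean cortical thickness of the generating
#'   field (default 2.5 mm).
#' @return object of class `hemisphere_pair`: `left`/`right` lists of
#'   [hemi_surface()]s (`white`, `gray`, `mid`), the generating
#'   `thickness` field, `n_vertices`, `radius`.
#' @export
make_hemisphere_pair <- function(subdivision = 4, radius = 50,
                                 center_offset_mm = 32,
                                 thickness_base_mm = 2.5) {
  stopifnot(subdivision >= 2)
  ico <- icosphere(subdivision)
  u <- ico$vertices
  deform <- 1 + 0.04 * smooth_sphere_field(u, 2L) +
    0.03 * smooth_sphere_field(u, 4L)
  r <- radius * deform
  thickness <- thickness_base_mm + 0.4 * smooth_sphere_field(u, 1L)
  right_center <- c(center_offset_mm, 0, 0)
  build <- function(offset_mm, hemi) {
    vr <- u * (r + offset_mm)
    vr <- sweep(vr, 2, right_center, "+")
    if (hemi == "left") vr[, 1] <- -vr[, 1]
    vr
  }
  mk <- function(hemi) {
    white <- build(0, hemi)
    gray <- build(0, hemi) + (if (hemi == "left")
      cbind(-u[, 1], u[, 2], u[, 3]) else u) * thickness
    mid <- (white + gray) / 2
    list(white = hemi_surface(white, ico$triangles, hemi, "white",
                              check = FALSE),
         gray = hemi_surface(gray, ico$triangles, hemi, "pial",
                             check = FALSE),
         mid = hemi_surface(mid, ico$triangles, hemi, "mid",
                            check = FALSE))
  }
  structure(list(left = mk("left"), right = mk("right"),
                 thickness = thickness, n_vertices = nrow(u),
                 radius = radius, units = u,
                 correspondence = seq_len(nrow(u))),
            class = "hemisphere_pair")
}

# per-channel generating model: mean level, amplitude of the smooth
# spatial field, noise sd (the "control sd" that lesion effect sizes are
# expressed in)
channel_model <- function() {
  data.frame(
    channel = FEATURE_CHANNELS,
    mean = c(2.5, 1.0, 0, 0, 100, 102, 104, 106, 108, 110, 4e-4),
    amplitude = c(0.4, 0.08, 3.0, 0.10, 4, 4, 4, 4, 4, 4, 1e-4),
    sd = c(0.25, 0.08, 0.8, 0.05, 5, 5, 5, 5, 5, 5, 2e-4),
    field = c(1L, 2L, 1L, 3L, 2L, 3L, 4L, 1L, 2L, 3L, 4L),
    stringsAsFactors = FALSE)
}

#' Default lesion effect sizes (control-sd units)
#'
#' The dysplasia signature the feature set targets: thickened cortex,
#' blurred (reduced) gray-white contrast, FLAIR hyperintensity through
#' cortical and subcortical depths, abnormal intrinsic curvature; sulcal
#' depth and mean curvature carry no injected effect.
#'
#' @param magnitude absolute effect size on affected channels (default 3).
#' @return named numeric vector over [FEATURE_CHANNELS].
#' @export
default_lesion_effects <- function(magnitude = 3) {
  e <- stats::setNames(numeric(length(FEATURE_CHANNELS)), FEATURE_CHANNELS)
  e["thickness"] <- magnitude
  e["gw_contrast"] <- -magnitude
  e[grep("^flair_", FEATURE_CHANNELS)] <- magnitude
  e["intrinsic_curvature"] <- magnitude
  e
}

#' Synthetic cohort specification
#'
#' Defaults state the simulated world: 8 lesional patients and 10 healthy
#' controls on a subdivision-4 icosphere pair; lesion areas drawn from a
#' lognormal with median 1185 mm^2 (scaled to the synthetic mesh by the
#' ratio of mesh area to a 90,000 mm^2 reference hemisphere) and truncated
#' below at a 300 mm^2-equivalent; effect sizes of 3 control sd on the
#' affected channels; one lesion-targeted electrode plus background
#' electrodes of 8 contacts at 3.5 mm spacing.
#'
#' @param n_patients,n_controls cohort sizes.
#' @param subdivision,radius mesh parameters (see
#'   [make_hemisphere_pair()]).
#' @param lesion_effects named effect-size vector (control-sd units).
#' @param lesion_median_area_mm2 real-scale lognormal median.
#' @param lesion_sdlog lognormal log-sd (1.15 calibrates the median
#'   absolute deviation to the 789/1185 ratio of the clinical lesions).
#' @param min_lesion_area_mm2 real-scale truncation floor.
#' @param reference_hemi_area_mm2 real hemisphere area used for scaling.
#' @param n_electrodes,n_contacts,contact_spacing_mm implantation layout.
#' @param soz_radius_mm,irritative_radius_mm contact labelling shells
#'   around the lesion patch.
#' @return list of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_patients = 8, n_controls = 10,
                                  subdivision = 4, radius = 50,
                                  lesion_effects = default_lesion_effects(),
                                  lesion_median_area_mm2 = 1185,
                                  lesion_sdlog = 1.15,
                                  min_lesion_area_mm2 = 300,
                                  reference_hemi_area_mm2 = 90000,
                                  n_electrodes = 6, n_contacts = 8,
                                  contact_spacing_mm = 3.5,
                                  soz_radius_mm = 10,
                                  irritative_radius_mm = 20) {
  stopifnot(n_patients >= 2, n_controls >= 2)
  structure(as.list(environment()), class = "synthetic_cohort_spec")
}

#' Generate one healthy-control feature set
#'
#' Every channel is a smooth spatial mean field (identical across
#' subjects and mirror-symmetric across hemispheres) plus i.i.d. Gaussian
#' vertex noise of the channel's control sd, independently per hemisphere.
#'
#' @param pair a `hemisphere_pair`.
#' @param seed integer seed.
#' @param model channel generating model (advanced use).
#' @return a raw-stage `feature_set`.
#' @export
generate_control <- function(pair, seed, model = channel_model()) {
  set.seed(seed)
  u <- icosphere_units(pair)
  nv <- pair$n_vertices
  mk <- function() {
    m <- matrix(0, nv, nrow(model),
                dimnames = list(NULL, model$channel))
    for (i in seq_len(nrow(model)))
      m[, i] <- model$mean[i] +
        model$amplitude[i] * smooth_sphere_field(u, model$field[i]) +
        stats::rnorm(nv, 0, model$sd[i])
    m
  }
  feature_set(mk(), mk(), stage = "raw")
}

# unit-sphere directions of the template vertices (shared by both
# hemispheres by construction)
icosphere_units <- function(pair) pair$units

#' Inject a lesion patch into a feature set
#'
#' Vertices within the geodesic radius of the center get per-channel
#' offsets of `effects * control_sd`, with a tapered cosine edge (full
#' effect out to 90% of the radius, cosine roll-off to zero at the rim).
#' The returned mask is the full patch (all vertices within the radius);
#' the contralateral hemisphere is untouched.
#'
#' @param fs a raw-stage `feature_set`.
#' @param pair the `hemisphere_pair` carrying the mesh.
#' @param center_vertex 1-based template vertex id of the lesion center.
#' @param hemisphere `"left"` or `"right"`.
#' @param radius_mm geodesic lesion radius (> 0).
#' @param effects named per-channel effect sizes in control-sd units.
#' @param model channel generating model (supplies the sd scale).
#' @return list with `features` (modified `feature_set`), `mask` (logical
#'   template vector), `hemisphere`, `center_vertex`, `radius_mm`,
#'   `area_mm2` (realized mask area).
#' @export
inject_lesion <- function(fs, pair, center_vertex, hemisphere, radius_mm,
                          effects = default_lesion_effects(),
                          model = channel_model()) {
  stopifnot(radius_mm > 0)
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  if (radius_mm > 0.45 * pi * pair$radius)
    stop("lesion radius exceeds hemisphere extent")
  surf <- pair[[hemisphere]]$mid
  # straight-line distance: on the near-spherical synthetic surface it
  # matches the true geodesic to <1% at these radii, whereas edge-path
  # Dijkstra overestimates by up to ~15% and would shrink the patch
  ctr <- surf$vertices[center_vertex, ]
  d <- sqrt(rowSums(sweep(surf$vertices, 2, ctr)^2))
  w <- numeric(length(d))
  core <- 0.9 * radius_mm
  w[d <= core] <- 1
  edge <- d > core & d <= radius_mm
  w[edge] <- 0.5 * (1 + cos(pi * (d[edge] - core) / (radius_mm - core)))
  mask <- d <= radius_mm
  sds <- stats::setNames(model$sd, model$channel)
  x <- fs[[hemisphere]]
  for (ch in names(effects)) {
    if (effects[[ch]] == 0) next
    x[, ch] <- x[, ch] + effects[[ch]] * sds[[ch]] * w
  }
  fs[[hemisphere]] <- x
  areas <- overlay_values(suppressWarnings(vertex_areas(surf)))
  list(features = fs, mask = mask, hemisphere = hemisphere,
       center_vertex = center_vertex, radius_mm = radius_mm,
       area_mm2 = sum(areas[mask]))
}

#' Generate linear sEEG electrode trajectories with labelled contacts
#'
#' Each electrode runs from a scalp-ward entry point straight to its
#' target, with `n_contacts` equally spaced contacts, the deepest at the
#' target. Contacts within `soz_radius_mm` of the designated lesion patch
#' are labelled `SOZ`, the next shell (up to `irritative_radius_mm`)
#' `irritative`, the rest `uninvolved`.
#'
#' @param pair a `hemisphere_pair`.
#' @param targets integer template vertex ids of electrode targets.
#' @param target_hemis hemisphere of each target.
#' @param mask_vertices template vertex ids of the true lesion patch.
#' @param mask_hemisphere hemisphere of the patch (no patch: all contacts
#'   `uninvolved`).
#' @param n_contacts,spacing_mm contact layout (defaults 8 and 3.5 mm).
#' @param soz_radius_mm,irritative_radius_mm labelling shells.
#' @return an `electrode_set`.
#' @export
generate_electrodes <- function(pair, targets, target_hemis,
                                mask_vertices = integer(),
                                mask_hemisphere = NULL,
                                n_contacts = 8, spacing_mm = 3.5,
                                soz_radius_mm = 10,
                                irritative_radius_mm = 20) {
  rows <- list()
  mask_xyz <- if (length(mask_vertices) && !is.null(mask_hemisphere))
    pair[[mask_hemisphere]]$mid$vertices[mask_vertices, , drop = FALSE]
  for (e in seq_along(targets)) {
    hemi <- target_hemis[[e]]
    surf <- pair[[hemi]]$mid
    target <- surf$vertices[targets[[e]], ]
    ctr <- colMeans(surf$vertices)
    outward <- target - ctr
    outward <- outward / sqrt(sum(outward^2))
    pos <- t(vapply(seq_len(n_contacts) - 1L,
                    function(k) target + k * spacing_mm * outward,
                    numeric(3)))
    lab <- rep("uninvolved", n_contacts)
    if (!is.null(mask_xyz)) {
      dmin <- apply(pos, 1, function(p)
        sqrt(min(colSums((t(mask_xyz) - p)^2))))
      lab[dmin < irritative_radius_mm] <- "irritative"
      lab[dmin < soz_radius_mm] <- "SOZ"
    }
    rows[[e]] <- data.frame(
      electrode = sprintf("%sE%d", toupper(substr(hemi, 1, 1)), e),
      contact = seq_len(n_contacts),
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      label = lab, stringsAsFactors = FALSE)
  }
  make_contacts(do.call(rbind, rows))
}

#' Generate a full synthetic cohort
#'
#' Controls, lesional patients (lesion specs realized from the spec's
#' area distribution), per-patient electrode implantations (one electrode
#' targeted at the lesion center plus background electrodes on the same
#' hemisphere), all deterministic from `seed`.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param seed integer master seed.
#' @return list of class `synthetic_cohort`: `pair`, `controls` (feature
#'   sets), `patients` (each with `id`, `features`, `mask`, `lesion`,
#'   `electrodes`, `implant_laterality`), `spec`, `seed`.
#' @export
generate_cohort <- function(spec = synthetic_cohort_spec(), seed = 1L) {
  pair <- make_hemisphere_pair(spec$subdivision, spec$radius)
  controls <- lapply(seq_len(spec$n_controls), function(i)
    generate_control(pair, seed = seed * 1000L + i))
  mesh_area <- sum(triangle_areas(pair$left$mid))
  scale <- mesh_area / spec$reference_hemi_area_mm2
  min_area <- spec$min_lesion_area_mm2 * scale
  max_area <- 0.2 * mesh_area
  patients <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    sd_i <- seed * 1000L + 500L + i
    set.seed(sd_i)
    hemi <- c("left", "right")[1L + (i %% 2L)]
    area <- Inf
    while (area < min_area || area > max_area)
      area <- stats::rlnorm(1, log(spec$lesion_median_area_mm2 * scale),
                            spec$lesion_sdlog)
    center <- sample.int(pair$n_vertices, 1)
    radius <- sqrt(area / pi)
    fs <- generate_control(pair, seed = sd_i + 10000L)
    les <- inject_lesion(fs, pair, center, hemi, radius,
                         effects = spec$lesion_effects)
    set.seed(sd_i + 20000L)
    bg <- sample(setdiff(seq_len(pair$n_vertices), which(les$mask)),
                 spec$n_electrodes - 1L)
    electrodes <- generate_electrodes(
      pair, targets = c(center, bg),
      target_hemis = rep(hemi, spec$n_electrodes),
      mask_vertices = which(les$mask), mask_hemisphere = hemi,
      n_contacts = spec$n_contacts, spacing_mm = spec$contact_spacing_mm,
      soz_radius_mm = spec$soz_radius_mm,
      irritative_radius_mm = spec$irritative_radius_mm)
    patients[[i]] <- list(id = sprintf("P%02d", i), features = les$features,
                          mask = list(hemisphere = hemi,
                                      vertices = which(les$mask)),
                          lesion = les[c("hemisphere", "center_vertex",
                                         "radius_mm", "area_mm2")],
                          electrodes = electrodes,
                          implant_laterality = hemi)
  }
  structure(list(pair = pair, controls = controls, patients = patients,
                 spec = spec, seed = seed),
            class = "synthetic_cohort")
}
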