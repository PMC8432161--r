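# Per-vertex feature channels and their preprocessing: depth-sampled
# intensities, smoothing specification, within/between-subject z-scoring,
# interhemispheric asymmetry, and assembly of the classifier design matrix.

#' Canonical feature channel names, in design-matrix order
#'
#' Cortical thickness, gray-white intensity contrast, sulcal depth, mean
#' curvature, FLAIR intensity at 25/50/75% cortical depth, at the
#' gray-white boundary and 0.5/1 mm subcortically, and intrinsic curvature.
#'
#' @export
FEATURE_CHANNELS <- c("thickness", "gw_contrast", "sulcal_depth",
                      "mean_curvature", "flair_25", "flair_50", "flair_75",
                      "flair_gw", "flair_sc05", "flair_sc10",
                      "intrinsic_curvature")

#' Default per-channel smoothing kernels (FWHM, mm)
#'
#' 10 mm for thickness, gray-white contrast and all FLAIR depth samples;
#' 20 mm for intrinsic curvature (stable across adjacent gyri/sulci);
#' no smoothing for mean curvature and sulcal depth.
#'
#' @return named numeric vector of FWHMs over [FEATURE_CHANNELS].
#' @export
smoothing_spec <- function() {
  fwhm <- stats::setNames(rep(10, length(FEATURE_CHANNELS)),
                          FEATURE_CHANNELS)
  fwhm[c("mean_curvature", "sulcal_depth")] <- 0
  fwhm["intrinsic_curvature"] <- 20
  fwhm
}

#' Construct a two-hemisphere feature set
#'
#' @param left,right numeric matrices, template vertices x channels, with
#'   column names from [FEATURE_CHANNELS].
#' @param stage processing stage: `"raw"`, `"smoothed"`, `"normalized"` or
#'   `"asymmetry-augmented"`.
#' @param asymmetry optional list of left/right asymmetry matrices (present
#'   only at the asymmetry-augmented stage).
#' @return object of class `feature_set`.
#' @export
feature_set <- function(left, right, stage = "raw", asymmetry = NULL) {
  stage <- match.arg(stage, c("raw", "smoothed", "normalized",
                              "asymmetry-augmented"))
  if (!identical(dim(left), dim(right)))
    stop("left/right feature matrices must have identical shape")
  if (is.null(colnames(left)) || is.null(colnames(right)))
    stop("feature matrices must carry channel column names")
  if (!is.null(asymmetry) && stage != "asymmetry-augmented")
    stop("asymmetry channels exist only at the asymmetry-augmented stage")
  structure(list(left = left, right = right, stage = stage,
                 asymmetry = asymmetry), class = "feature_set")
}

stage_rank <- function(stage) {
  match(stage, c("raw", "smoothed", "normalized", "asymmetry-augmented"))
}

# ---- Depth-sampled intensities ------------------------------------------

trilinear_sample <- function(volume, vox) {
  d <- dim(volume)
  x <- vox[, 1]; y <- vox[, 2]; z <- vox[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  inside <- x0 >= 0 & y0 >= 0 & z0 >= 0 &
    x0 <= d[1] - 2 & y0 <= d[2] - 2 & z0 <= d[3] - 2
  out <- rep(NA_real_, nrow(vox))
  if (!any(inside)) return(out)
  xi <- x0[inside]; yi <- y0[inside]; zi <- z0[inside]
  fx <- x[inside] - xi; fy <- y[inside] - yi; fz <- z[inside] - zi
  at <- function(dx, dy, dz)  # 1-based array lookup of 0-based voxel
    volume[cbind(xi + dx + 1, yi + dy + 1, zi + dz + 1)]
  out[inside] <-
    at(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
    at(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
    at(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    at(1, 1, 0) * fx * fy * (1 - fz) +
    at(1, 0, 1) * fx * (1 - fy) * fz +
    at(0, 1, 1) * (1 - fx) * fy * fz +
    at(1, 1, 1) * fx * fy * fz
  out
}

#' Sample an intensity volume at a cortical depth or subcortical offset
#'
#' Sample points are `white + depth_fraction * (gray - white)` for cortical
#' depth fractions, or `white - subcortical_mm * unit(gray - white)` for
#' subcortical offsets. The volume is interpolated trilinearly; samples
#' falling outside the volume are masked `NA` with one warning reporting
#' the count.
#'
#' @param volume list with `data` (3-d array) and `vox2ras` (4x4 affine,
#'   0-based voxel indices), as returned by [read_mgh()]/[read_nifti()].
#' @param white,gray vertex-paired [hemi_surface()]s of one hemisphere.
#' @param depth_fraction cortical depth in `[0, 1]` (0 = white surface).
#' @param subcortical_mm offset below the white surface in mm (used when
#'   `depth_fraction` is `NULL`).
#' @param name overlay name.
#' @return an [overlay()] of sampled intensities.
#' @export
sample_at_depth <- function(volume, white, gray, depth_fraction = NULL,
                            subcortical_mm = NULL, name = "intensity") {
  if (n_vertices(white) != n_vertices(gray))
    stop("white/gray surfaces must be vertex-paired")
  w <- white$vertices; g <- gray$vertices
  if (!is.null(depth_fraction)) {
    stopifnot(depth_fraction >= 0, depth_fraction <= 1)
    pts <- w + depth_fraction * (g - w)
  } else if (!is.null(subcortical_mm)) {
    stopifnot(subcortical_mm >= 0)
    dirv <- g - w
    len <- sqrt(rowSums(dirv^2))
    len[len == 0] <- 1
    pts <- w - subcortical_mm * dirv / len
  } else stop("give either depth_fraction or subcortical_mm")
  ras2vox <- solve(volume$vox2ras)
  vox <- cbind(pts, 1) %*% t(ras2vox)
  vals <- trilinear_sample(volume$data, vox[, 1:3, drop = FALSE])
  n_out <- sum(is.na(vals))
  if (n_out > 0)
    warning(sprintf("%d sample point(s) outside the volume, masked NA",
                    n_out))
  overlay(vals, name = name)
}

# ---- Normalization ------------------------------------------------------

sd_floor_for <- function(global_sd) 1e-6 * max(global_sd, .Machine$double.eps)

#' Within-subject z-scoring of an overlay
#'
#' Centers and scales by the mean and population standard deviation over
#' the subject's non-masked vertices, adjusting for inter-individual
#' offsets (e.g. age-related global thickness differences). A standard
#' deviation below the floor yields all zeros with a warning.
#'
#' @param x an [overlay()] or numeric vector (>= 2 non-masked values).
#' @return z-scored [overlay()] (mean 0, population sd 1).
#' @export
normalize_within_subject <- function(x) {
  v <- overlay_values(x)
  ok <- !is.na(v)
  if (sum(ok) < 2) stop("need >= 2 non-masked vertices to z-score")
  mu <- mean(v[ok])
  sdv <- sqrt(mean((v[ok] - mu)^2))
  if (sdv < sd_floor_for(abs(mu) + sdv)) {
    warning("overlay is (near-)constant; within-subject z-scores set to 0")
    v[ok] <- 0
  } else {
    v[ok] <- (v[ok] - mu) / sdv
  }
  overlay(v, name = attr(x, "name") %||% "overlay", units = "z")
}

#' Estimate per-vertex control statistics
#'
#' Per-vertex mean and standard deviation (sample sd, n-1) of each channel
#' over the healthy-control population on the symmetric template. Both
#' hemispheres of each control map onto the same template index space and
#' are pooled, giving `2 * n_controls` samples per template vertex.
#'
#' @param controls list of `feature_set`s at a common stage.
#' @return object of class `control_stats`: per-channel `mean` and `sd`
#'   matrices (vertices x channels), `sd_floor` per channel, `n_controls`.
#' @export
control_stats <- function(controls) {
  stopifnot(length(controls) >= 2)
  channels <- colnames(controls[[1]]$left)
  stacked <- lapply(controls, function(fs) list(fs$left, fs$right))
  stacked <- unlist(stacked, recursive = FALSE)
  nv <- nrow(stacked[[1]])
  mu <- sdm <- matrix(0, nv, length(channels),
                      dimnames = list(NULL, channels))
  for (ch in channels) {
    m <- vapply(stacked, function(x) x[, ch], numeric(nv))
    mu[, ch] <- rowMeans(m)
    sdm[, ch] <- apply(m, 1, stats::sd)
  }
  floors <- vapply(channels, function(ch)
    sd_floor_for(stats::sd(as.numeric(
      vapply(stacked, function(x) x[, ch], numeric(nv))))), numeric(1))
  structure(list(mean = mu, sd = sdm, sd_floor = floors,
                 n_controls = length(controls)),
            class = "control_stats")
}

#' Between-subject z-scoring against control statistics
#'
#' Normalizes a subject's per-vertex channel by the control population's
#' per-vertex mean and standard deviation, adjusting for normal regional
#' variability. Standard deviations below the channel's floor are replaced
#' by the floor.
#'
#' @param x overlay or numeric vector on the template.
#' @param stats a [control_stats()] object.
#' @param channel channel name present in `stats`.
#' @return z-scored [overlay()].
#' @export
normalize_between_subjects <- function(x, stats, channel) {
  if (!channel %in% colnames(stats$mean))
    stop("channel absent from control stats: ", channel)
  v <- overlay_values(x)
  if (length(v) != nrow(stats$mean))
    stop("overlay length does not match control stats template")
  sdv <- pmax(stats$sd[, channel], stats$sd_floor[[channel]])
  overlay((v - stats$mean[, channel]) / sdv,
          name = paste0(channel, "_zb"), units = "z")
}

#' Interhemispheric asymmetry of a feature on the symmetric template
#'
#' On the bilaterally symmetric template, homologous vertices share an
#' index, so asymmetry is a per-vertex difference: the left asymmetry map
#' is `left - right` and the right map `right - left` (exact negatives).
#'
#' @param left,right overlays/vectors on the common template index space.
#' @return list with `left` and `right` asymmetry [overlay()]s.
#' @export
interhemispheric_asymmetry <- function(left, right) {
  l <- overlay_values(left); r <- overlay_values(right)
  if (length(l) != length(r))
    stop("hemisphere overlays differ in length: ", length(l), " vs ",
         length(r))
  list(left = overlay(l - r, name = "asymmetry"),
       right = overlay(r - l, name = "asymmetry"))
}

# ---- Full preprocessing and design matrix -------------------------------

#' Run the feature preprocessing chain on a subject
#'
#' smooth (per-channel FWHM) -> within-subject z (pooled over both
#' hemispheres) -> between-subject z against control stats -> asymmetry.
#'
#' @param fs a raw-stage `feature_set`.
#' @param surface template [hemi_surface()] carrying the mesh geometry
#'   (shared by both hemispheres of the symmetric template).
#' @param stats [control_stats()] built from controls processed through the
#'   same smoothing and within-subject steps (skipped when `NULL`, e.g.
#'   while building those stats).
#' @param weights named list of precomputed [smoothing_weights()] operators
#'   keyed by FWHM (e.g. `"10"`, `"20"`); computed on the fly if missing.
#' @param fwhm named per-channel FWHM vector (default [smoothing_spec()]).
#' @param zscore_all z-score every channel (default) or only the channels
#'   conventionally described as normalized (all but sulcal depth and mean
#'   curvature).
#' @return `feature_set` at stage `"normalized"` (no stats: stops after the
#'   within-subject step) or `"asymmetry-augmented"`.
#' @export
preprocess_features <- function(fs, surface, stats = NULL, weights = NULL,
                                fwhm = smoothing_spec(),
                                zscore_all = TRUE) {
  stopifnot(inherits(fs, "feature_set"))
  if (stage_rank(fs$stage) > 1) stop("expected a raw-stage feature set")
  channels <- colnames(fs$left)
  zchannels <- if (zscore_all) channels else
    setdiff(channels, c("sulcal_depth", "mean_curvature"))
  sm <- list(left = fs$left, right = fs$right)
  for (ch in channels) {
    f <- fwhm[[ch]]
    if (is.null(f) || f == 0) next
    key <- as.character(f)
    if (is.null(weights[[key]]))
      weights[[key]] <- smoothing_weights(surface, f)
    for (h in c("left", "right"))
      sm[[h]][, ch] <- overlay_values(
        smooth_overlay(surface, sm[[h]][, ch], f, weights[[key]]))
  }
  for (ch in zchannels) {
    z <- normalize_within_subject(c(sm$left[, ch], sm$right[, ch]))
    nv <- nrow(sm$left)
    sm$left[, ch] <- overlay_values(z)[seq_len(nv)]
    sm$right[, ch] <- overlay_values(z)[nv + seq_len(nv)]
  }
  if (is.null(stats))
    return(feature_set(sm$left, sm$right, stage = "normalized"))
  for (ch in zchannels) {
    sm$left[, ch] <- overlay_values(
      normalize_between_subjects(sm$left[, ch], stats, ch))
    sm$right[, ch] <- overlay_values(
      normalize_between_subjects(sm$right[, ch], stats, ch))
  }
  asym <- list(left = sm$left, right = sm$right)  # shape template
  for (ch in channels) {
    a <- interhemispheric_asymmetry(sm$left[, ch], sm$right[, ch])
    asym$left[, ch] <- overlay_values(a$left)
    asym$right[, ch] <- overlay_values(a$right)
  }
  feature_set(sm$left, sm$right, stage = "asymmetry-augmented",
              asymmetry = asym)
}

#' Assemble the per-vertex classifier design matrix for one hemisphere
#'
#' Columns are the feature channels in [FEATURE_CHANNELS] order followed by
#' their interhemispheric-asymmetry counterparts (`asym_*`), 22 columns in
#' total; rows are template vertices of the requested hemisphere.
#'
#' @param fs an asymmetry-augmented `feature_set`.
#' @param hemisphere `"left"` or `"right"`.
#' @return numeric matrix, vertices x 22.
#' @export
build_feature_matrix <- function(fs, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  if (fs$stage != "asymmetry-augmented")
    stop("feature set must be at the asymmetry-augmented stage")
  miss <- setdiff(FEATURE_CHANNELS, colnames(fs[[hemisphere]]))
  if (length(miss))
    stop("missing feature channel(s): ", paste(miss, collapse = ", "))
  x <- fs[[hemisphere]][, FEATURE_CHANNELS, drop = FALSE]
  a <- fs$asymmetry[[hemisphere]][, FEATURE_CHANNELS, drop = FALSE]
  colnames(a) <- paste0("asym_", FEATURE_CHANNELS)
  cbind(x, a)
}
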