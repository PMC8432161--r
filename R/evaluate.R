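# Cohort-level evaluation: feature preparation, leave-one-out
# cross-validation of the vertex classifier, and control-cohort
# specificity.

#' Prepare classifier-ready features for a synthetic cohort
#'
#' Runs the full preprocessing chain for every subject: smoothing,
#' within-subject z-scoring, between-subject z-scoring against control
#' statistics built from the (smoothed, within-z-scored) controls, and
#' interhemispheric asymmetry. Smoothing operators are computed once on
#' the shared template mesh and reused.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param zscore_all z-score every channel (see [preprocess_features()]).
#' @return list of class `prepared_cohort`: `pair`, `stats`,
#'   `control_matrices` (per control, list of left/right design
#'   matrices), `subjects` (per patient: `id`, `features`, `matrices`,
#'   `mask`, `electrodes`, `implant_laterality`), `areas`, `weights`.
#' @export
prepare_cohort_features <- function(cohort, zscore_all = TRUE) {
  pair <- cohort$pair
  surf <- pair$left$mid  # mirror geometry: one operator serves both sides
  fwhm <- smoothing_spec()
  weights <- list()
  dist <- geodesic_distances(surf)
  for (f in sort(unique(fwhm[fwhm > 0])))
    weights[[as.character(f)]] <- smoothing_weights(surf, f,
                                                    distances = dist)
  half <- lapply(cohort$controls, preprocess_features, surface = surf,
                 stats = NULL, weights = weights, fwhm = fwhm,
                 zscore_all = zscore_all)
  stats <- control_stats(half)
  full <- function(fs) preprocess_features(fs, surf, stats = stats,
                                           weights = weights, fwhm = fwhm,
                                           zscore_all = zscore_all)
  controls_aug <- lapply(cohort$controls, full)
  control_matrices <- lapply(controls_aug, function(fs)
    list(left = build_feature_matrix(fs, "left"),
         right = build_feature_matrix(fs, "right")))
  subjects <- lapply(cohort$patients, function(p) {
    fs <- full(p$features)
    list(id = p$id, features = fs,
         matrices = list(left = build_feature_matrix(fs, "left"),
                         right = build_feature_matrix(fs, "right")),
         mask = p$mask, electrodes = p$electrodes,
         implant_laterality = p$implant_laterality)
  })
  areas <- overlay_values(suppressWarnings(vertex_areas(surf)))
  structure(list(pair = pair, stats = stats,
                 control_matrices = control_matrices,
                 subjects = subjects, areas = areas, weights = weights),
            class = "prepared_cohort")
}

stack_control_matrix <- function(prepared) {
  do.call(rbind, unlist(lapply(prepared$control_matrices,
                               function(m) list(m$left, m$right)),
                        recursive = FALSE))
}

subjects_for_training <- function(prepared, exclude = integer()) {
  idx <- setdiff(seq_along(prepared$subjects), exclude)
  lapply(prepared$subjects[idx], function(s)
    list(id = s$id, features = s$features, mask = s$mask))
}

predict_subject_clusters <- function(model, threshold, matrices, pair,
                                     min_area_mm2, areas) {
  cl <- c(extract_clusters(pair$left$mid, predict_vertices(model,
                                                           matrices$left),
                           threshold, min_area_mm2, areas),
          extract_clusters(pair$right$mid,
                           predict_vertices(model, matrices$right),
                           threshold, min_area_mm2, areas))
  rank_clusters(cl)
}

#' Leave-one-out cross-validation of the vertex classifier
#'
#' For each held-out patient: the network is trained on the remaining
#' patients (balanced lesional/contralateral sampling), the decision
#' threshold is chosen by the Youden index on that training set only, the
#' held-out patient's two hemispheres are scored and clustered, and the
#' lesion counts as detected if any suprathreshold cluster shares a vertex
#' with the manual mask. The hidden-layer size comes from the control
#' cohort's PCA (controls are disjoint from the patients, so it is shared
#' across folds).
#'
#' @param prepared a `prepared_cohort`.
#' @param seed integer seed (training-set sampling and weight init).
#' @param min_area_mm2 cluster area filter (default 50).
#' @param grid Youden threshold grid.
#' @return list of class `loocv_result`: `sensitivity`, `folds`
#'   (per-subject: detected flag, threshold, cluster count, training
#'   subject ids — the left-out id never appears), `hidden_size`.
#' @export
loocv <- function(prepared, seed = 1L, min_area_mm2 = 50,
                  grid = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(length(prepared$subjects) >= 2)
  hidden <- select_hidden_size(stack_control_matrix(prepared))
  folds <- list()
  for (i in seq_along(prepared$subjects)) {
    ts <- assemble_training_set(subjects_for_training(prepared, i),
                                seed = seed + i)
    model <- suppressWarnings(
      train_network(ts, hidden_size = hidden, seed = seed + i))
    thr <- youden_threshold(predict_vertices(model, ts$x), ts$y, grid)
    s <- prepared$subjects[[i]]
    clusters <- predict_subject_clusters(model, thr, s$matrices,
                                         prepared$pair, min_area_mm2,
                                         prepared$areas)
    mask_vec <- numeric(prepared$pair$n_vertices)
    mask_vec[s$mask$vertices] <- 1
    same_hemi <- Filter(function(cl) cl$hemisphere == s$mask$hemisphere,
                        clusters)
    detected <- any(vapply(same_hemi, overlap_with_mask, logical(1),
                           mask = mask_vec))
    top_overlap <- length(clusters) > 0 &&
      clusters[[1]]$hemisphere == s$mask$hemisphere &&
      overlap_with_mask(clusters[[1]], mask_vec)
    folds[[i]] <- list(subject = s$id, detected = detected,
                       top_cluster_overlaps = top_overlap,
                       threshold = as.numeric(thr),
                       n_clusters = length(clusters),
                       training_subjects = unique(ts$subject))
  }
  structure(list(
    sensitivity = mean(vapply(folds, `[[`, logical(1), "detected")),
    folds = folds, hidden_size = hidden), class = "loocv_result")
}

#' Specificity of the full-cohort model on healthy controls
#'
#' Trains on every patient, fixes the Youden threshold on that training
#' set, scores and clusters each control's two hemispheres; any cluster in
#' a control is a false positive. Specificity is the fraction of controls
#' with zero clusters.
#'
#' @inheritParams loocv
#' @return list of class `specificity_result`: `specificity`,
#'   `fp_clusters` (per control), `model`, `threshold`.
#' @export
control_specificity <- function(prepared, seed = 1L, min_area_mm2 = 50,
                                grid = seq(0.01, 0.99, by = 0.01)) {
  hidden <- select_hidden_size(stack_control_matrix(prepared))
  ts <- assemble_training_set(subjects_for_training(prepared),
                              seed = seed)
  model <- suppressWarnings(
    train_network(ts, hidden_size = hidden, seed = seed))
  thr <- youden_threshold(predict_vertices(model, ts$x), ts$y, grid)
  fp <- vapply(prepared$control_matrices, function(m)
    length(predict_subject_clusters(model, thr, m, prepared$pair,
                                    min_area_mm2, prepared$areas)),
    integer(1))
  structure(list(specificity = mean(fp == 0), fp_clusters = fp,
                 model = model, threshold = as.numeric(thr)),
            class = "specificity_result")
}
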