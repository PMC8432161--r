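# Cohort-level tallies mirroring the clinical summary statistics, plus
# end-to-end pipeline orchestration on synthetic cohorts.

round_half_up <- function(x) floor(x + 0.5) * sign(sign(x) + 0.5)

is_fcd <- function(h) h %in% c("FCD IIA", "FCD IIB", "FCD II")

#' Summary tallies over a patient cohort table
#'
#' Reproduces the flowchart counts from the validated records: focal /
#' mesial-temporal / diffuse-or-likely-focal split, concordance of the
#' automated clusters with the seizure onset zone among focal patients and
#' among the histology-confirmed dysplasias, resective-surgery counts,
#' cluster count statistics (sample sd), and the count of focal patients
#' not seizure-free after surgery who carry at least one cluster.
#' Percentages are rounded to the nearest integer, half away from zero.
#'
#' @param records a `patient_cohort` from [read_cohort_table()].
#' @return list of class `cohort_summary`.
#' @export
tally_cohort <- function(records) {
  if (nrow(records) == 0) stop("empty cohort")
  focal <- records$seeg_outcome == "focal"
  conc <- records$concordance == "yes"
  fcd <- is_fcd(records$histology)
  pct <- function(num, den) as.integer(round_half_up(100 * num / den))
  n_focal <- sum(focal)
  n_focal_concordant <- sum(focal & conc)
  n_fcd <- sum(focal & fcd)
  n_fcd_concordant <- sum(focal & fcd & conc)
  not_free <- focal & records$seizure_free == "no"
  out <- list(
    n_total = nrow(records),
    n_focal = n_focal,
    n_mtle = sum(records$seeg_outcome == "mTLE"),
    n_diffuse_or_likely = sum(records$seeg_outcome %in%
                                c("diffuse", "likely-focal")),
    n_focal_concordant = n_focal_concordant,
    focal_concordance_pct = pct(n_focal_concordant, n_focal),
    n_fcd_histology = n_fcd,
    n_fcd_concordant = n_fcd_concordant,
    fcd_concordance_pct = pct(n_fcd_concordant, n_fcd),
    n_focal_surgery = sum(focal & records$surgery == "yes"),
    n_focal_surgery_seizure_free = sum(focal & records$surgery == "yes" &
                                         records$seizure_free == "yes"),
    cluster_mean = mean(records$n_clusters),
    cluster_sd = stats::sd(records$n_clusters),
    cluster_range = range(records$n_clusters),
    n_focal_not_seizure_free = sum(not_free),
    n_focal_not_seizure_free_with_clusters = sum(not_free &
                                                   records$n_clusters >= 1))
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d sEEG patients\n", x$n_total))
  cat(sprintf("  focal SOZ: %d | mesial temporal: %d | diffuse/likely: %d\n",
              x$n_focal, x$n_mtle, x$n_diffuse_or_likely))
  cat(sprintf("  concordant among focal: %d/%d (%d%%)\n",
              x$n_focal_concordant, x$n_focal, x$focal_concordance_pct))
  cat(sprintf("  concordant among FCD histology: %d/%d (%d%%)\n",
              x$n_fcd_concordant, x$n_fcd_histology,
              x$fcd_concordance_pct))
  cat(sprintf("  focal patients with resective surgery: %d (%d seizure-free)\n",
              x$n_focal_surgery, x$n_focal_surgery_seizure_free))
  cat(sprintf("  clusters per patient: %.2f +/- %.2f (range %d-%d)\n",
              x$cluster_mean, x$cluster_sd, x$cluster_range[1],
              x$cluster_range[2]))
  cat(sprintf("  focal, not seizure-free, with >= 1 cluster: %d of %d\n",
              x$n_focal_not_seizure_free_with_clusters,
              x$n_focal_not_seizure_free))
  invisible(x)
}

PIPELINE_CONFIG_KEYS <- c("seed", "out_dir", "cohort", "min_area_mm2",
                          "distance_threshold_mm", "top_k",
                          "threshold_grid_step", "power_target",
                          "power_confidence", "power_cohorts")

#' Run the full synthetic pipeline end to end
#'
#' Stages, in order: simulate -> features -> classify (leave-one-out) ->
#' cluster -> colocalize -> plan -> report. Every held-out patient's
#' clusters come from a model that never saw that patient; concordance
#' with the simulated seizure onset zone, extra-electrode counts and the
#' prospective power calculation are derived from those clusters. Rerun
#' with the same config is bit-identical.
#'
#' @param config list with keys: `seed`; optional `out_dir` (writes
#'   cluster manifests, contact tables and a JSON summary); `cohort`
#'   (argument list for [synthetic_cohort_spec()]); `min_area_mm2` (50);
#'   `distance_threshold_mm` (10); `top_k` (3); `threshold_grid_step`
#'   (0.01); `power_target` (10); `power_confidence` (0.9);
#'   `power_cohorts` (1000). Unknown keys raise an error before any
#'   computation.
#' @return list of class `pipeline_result`: `loocv`, `specificity`,
#'   `patients` (per patient: clusters manifest, colocalization,
#'   concordance call, extra electrodes), `records` (synthetic
#'   `patient_cohort`), `summary` ([tally_cohort()] output), `power`
#'   (contribution probability and minimum prospective cohort size),
#'   `config` echo.
#' @export
run_pipeline <- function(config = list(seed = 1L)) {
  unknown <- setdiff(names(config), PIPELINE_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  seed <- as.integer(config$seed %||% 1L)
  min_area <- config$min_area_mm2 %||% 50
  dist_thr <- config$distance_threshold_mm %||% 10
  top_k <- config$top_k %||% 3
  step <- config$threshold_grid_step %||% 0.01
  grid <- seq(step, 1 - step, by = step)
  spec <- do.call(synthetic_cohort_spec, config$cohort %||% list())
  cohort <- generate_cohort(spec, seed = seed)
  prepared <- prepare_cohort_features(cohort)
  cv <- loocv(prepared, seed = seed, min_area_mm2 = min_area, grid = grid)
  sp <- control_specificity(prepared, seed = seed,
                            min_area_mm2 = min_area, grid = grid)
  surfaces <- list(left = prepared$pair$left$mid,
                   right = prepared$pair$right$mid)
  pconf <- planning_config(top_k = top_k,
                           distance_threshold_mm = dist_thr,
                           target_successes = config$power_target %||% 10,
                           confidence = config$power_confidence %||% 0.90,
                           n_cohorts = config$power_cohorts %||% 1000,
                           seed = seed)
  patients <- list(); recs <- list()
  for (i in seq_along(prepared$subjects)) {
    s <- prepared$subjects[[i]]
    ts <- assemble_training_set(subjects_for_training(prepared, i),
                                seed = seed + i)
    model <- suppressWarnings(
      train_network(ts, hidden_size = cv$hidden_size, seed = seed + i))
    thr <- youden_threshold(predict_vertices(model, ts$x), ts$y, grid)
    clusters <- predict_subject_clusters(model, thr, s$matrices,
                                         prepared$pair, min_area,
                                         prepared$areas)
    coloc <- assess_colocalization(clusters, s$electrodes, surfaces,
                                   threshold_mm = dist_thr)
    concordance <- classify_patient(coloc, "focal")
    planned <- filter_clusters_for_planning(clusters,
                                            s$implant_laterality, pconf)
    extra <- count_extra_electrodes(planned, s$electrodes, surfaces,
                                    pconf)
    patients[[i]] <- list(id = s$id, clusters = clusters,
                          manifest = clusters_manifest(clusters),
                          colocalization = coloc,
                          concordance = concordance,
                          extra_electrodes = extra)
    recs[[i]] <- data.frame(
      patient = s$id, seeg_indication = "Lesion-negative",
      seeg_outcome = "Focal", n_clusters = length(clusters),
      concordance = if (concordance == "yes") "Y" else "N",
      surgery = "N", histology = "n.a.", outcome = "n.a.",
      followup_months = "n.a.", stringsAsFactors = FALSE)
  }
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(do.call(rbind, recs), tmp, row.names = FALSE)
  records <- read_cohort_table(tmp)
  unlink(tmp)
  p_hat <- mean(vapply(patients, function(p) p$concordance == "yes",
                       logical(1)))
  min_n <- power_min_cohort(p_hat, target = pconf$target_successes,
                            confidence = pconf$confidence,
                            n_cohorts = pconf$n_cohorts, seed = seed)
  result <- structure(list(
    loocv = cv, specificity = sp, patients = patients, records = records,
    summary = tally_cohort(records),
    power = list(contribution_probability = p_hat,
                 min_cohort_size = min_n),
    extra_electrodes_total = sum(vapply(patients, `[[`, numeric(1),
                                        "extra_electrodes")),
    config = config, seed = seed), class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (p in result$patients) {
    utils::write.csv(p$manifest,
                     file.path(out_dir, paste0(p$id, "_clusters.csv")),
                     row.names = FALSE)
  }
  summary <- list(
    seed = result$seed,
    sensitivity = result$loocv$sensitivity,
    specificity = result$specificity$specificity,
    hidden_size = result$loocv$hidden_size,
    extra_electrodes_total = result$extra_electrodes_total,
    contribution_probability = result$power$contribution_probability,
    min_cohort_size = result$power$min_cohort_size)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Write a synthetic cohort to disk in standard formats
#'
#' Surfaces as FreeSurfer binary meshes, feature channels and lesion masks
#' as curv overlays, contacts as CSV, an identity contact-to-surface
#' affine, and a cohort CSV — the layout the command-line `simulate`
#' subcommand produces.
#'
#' @param cohort a `synthetic_cohort`.
#' @param out_dir output directory (created).
#' @return `out_dir`, invisibly.
#' @export
write_cohort_dir <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pair <- cohort$pair
  for (h in c("left", "right"))
    for (k in c("white", "gray", "mid"))
      write_surface(pair[[h]][[k]],
                    file.path(out_dir, sprintf("%s.%s.surf", h, k)))
  dump_fs <- function(fs, prefix) {
    for (h in c("left", "right"))
      for (ch in colnames(fs[[h]]))
        write_curv(fs[[h]][, ch],
                   file.path(out_dir, sprintf("%s_%s_%s.curv",
                                              prefix, h, ch)))
  }
  for (i in seq_along(cohort$controls))
    dump_fs(cohort$controls[[i]], sprintf("control%02d", i))
  for (p in cohort$patients) {
    dump_fs(p$features, p$id)
    mask <- numeric(pair$n_vertices)
    mask[p$mask$vertices] <- 1
    write_curv(mask, file.path(out_dir, sprintf("%s_mask_%s.curv",
                                                p$id, p$mask$hemisphere)))
    write_contacts(p$electrodes,
                   file.path(out_dir, sprintf("%s_contacts.csv", p$id)))
  }
  write_affine(diag(4), file.path(out_dir, "contacts_to_surface.txt"))
  invisible(out_dir)
}
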