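# Prospective-use analytics: which clusters would have been implanted,
# how many extra electrodes that needs, and the cohort power simulation.

#' Planning configuration
#'
#' @param top_k keep at most this many top-ranked clusters (default 3).
#' @param distance_threshold_mm a cluster with no contact within this
#'   distance needs an extra electrode (default 10).
#' @param exclude_contralateral drop clusters contralateral to a
#'   unilateral implantation (default TRUE).
#' @param n_cohorts Monte-Carlo cohorts for the power simulation.
#' @param confidence required probability of reaching the target.
#' @param target_successes required number of positive contributions.
#' @param contribution_probability per-patient contribution probability
#'   (estimate from a cohort table, e.g. concordant/total).
#' @param seed RNG seed for the simulation.
#' @return list of class `planning_config`.
#' @export
planning_config <- function(top_k = 3, distance_threshold_mm = 10,
                            exclude_contralateral = TRUE,
                            n_cohorts = 1000, confidence = 0.90,
                            target_successes = 10,
                            contribution_probability = NA_real_,
                            seed = 1L) {
  stopifnot(top_k >= 1, distance_threshold_mm > 0, n_cohorts >= 1,
            confidence > 0, confidence < 1, target_successes >= 0)
  if (!is.na(contribution_probability))
    stopifnot(contribution_probability >= 0, contribution_probability <= 1)
  structure(list(top_k = top_k,
                 distance_threshold_mm = distance_threshold_mm,
                 exclude_contralateral = exclude_contralateral,
                 n_cohorts = n_cohorts, confidence = confidence,
                 target_successes = target_successes,
                 contribution_probability = contribution_probability,
                 seed = seed),
            class = "planning_config")
}

#' Filter clusters for prospective implantation planning
#'
#' Applies the three exclusion rules in order: (1) clusters on the
#' hemisphere contralateral to a unilateral implantation; (2) clusters
#' flagged as obvious artifacts (`artifact_flag`, set manually); (3)
#' clusters outside the top `top_k` by rank.
#'
#' @param clusters ranked `lp_cluster` list (see [rank_clusters()]).
#' @param implant_laterality `"left"`, `"right"` or `"bilateral"`.
#' @param config a [planning_config()].
#' @return the surviving clusters.
#' @export
filter_clusters_for_planning <- function(clusters, implant_laterality,
                                         config = planning_config()) {
  implant_laterality <- match.arg(implant_laterality,
                                  c("left", "right", "bilateral"))
  if (length(clusters) == 0) return(clusters)
  if (any(is.na(vapply(clusters, `[[`, integer(1), "rank"))))
    stop("clusters must be ranked before planning")
  if (config$exclude_contralateral && implant_laterality != "bilateral")
    clusters <- Filter(function(cl) cl$hemisphere == implant_laterality,
                       clusters)
  clusters <- Filter(function(cl) !isTRUE(cl$artifact_flag), clusters)
  rk <- vapply(clusters, `[[`, integer(1), "rank")
  clusters[order(rk)][seq_len(min(config$top_k, length(clusters)))]
}

#' Count extra electrodes needed to sample the planned clusters
#'
#' A filtered cluster already within `distance_threshold_mm` of ANY
#' implanted contact is concordant and needs no new electrode; every other
#' cluster requires one additional electrode (rule of thumb: one electrode
#' per unsampled cluster).
#'
#' @param clusters filtered `lp_cluster` list.
#' @param contacts an `electrode_set` in surface space.
#' @param surfaces named list of [hemi_surface()]s (`left`, `right`).
#' @param config a [planning_config()].
#' @return integer count of extra electrodes.
#' @export
count_extra_electrodes <- function(clusters, contacts, surfaces,
                                   config = planning_config()) {
  if (length(clusters) == 0) return(0L)
  xyz <- as.matrix(contacts[, c("x", "y", "z")])
  needs <- vapply(clusters, function(cl) {
    d <- apply(xyz, 1, function(p)
      cluster_contact_distance(cl, surfaces[[cl$hemisphere]], p))
    min(d) >= config$distance_threshold_mm
  }, logical(1))
  sum(needs)
}

#' Minimum prospective cohort size for a contribution target
#'
#' Smallest `n` such that a cohort of `n` patients, each contributing with
#' probability `p`, yields at least `target` positive contributions with
#' probability at least `confidence`. The Monte-Carlo path simulates
#' `n_cohorts` binomial cohorts per candidate `n` (seeded); the exact path
#' evaluates the binomial tail and serves as the simulation's oracle.
#'
#' @param p per-patient contribution probability in `[0, 1]`.
#' @param target required number of contributions (default 10).
#' @param confidence required probability (default 0.90).
#' @param n_cohorts simulated cohorts per candidate size (default 1000).
#' @param seed RNG seed (Monte-Carlo path).
#' @param method `"monte-carlo"` (default) or `"exact"`.
#' @param n_max search cap.
#' @return the minimum cohort size, or `Inf` when no finite size can meet
#'   the target (e.g. `p = 0` with a positive target).
#' @export
power_min_cohort <- function(p, target = 10, confidence = 0.90,
                             n_cohorts = 1000, seed = 1L,
                             method = c("monte-carlo", "exact"),
                             n_max = 100000L) {
  method <- match.arg(method)
  stopifnot(p >= 0, p <= 1, target >= 0, confidence > 0, confidence < 1)
  if (target == 0) return(0L)
  if (p == 0) {
    warning("contribution probability 0 with a positive target: ",
            "no finite cohort size suffices")
    return(Inf)
  }
  if (method == "monte-carlo") set.seed(seed)
  for (n in seq.int(target, n_max)) {
    frac <- if (method == "exact") {
      stats::pbinom(target - 1, n, p, lower.tail = FALSE)
    } else {
      mean(stats::rbinom(n_cohorts, n, p) >= target)
    }
    if (frac >= confidence) return(as.integer(n))
  }
  warning("search cap reached without meeting the confidence level")
  Inf
}
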