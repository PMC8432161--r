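# Conversion of per-vertex lesion scores into ranked candidate clusters.

new_cluster <- function(vertices, hemisphere, area, mean_pred, centroid) {
  structure(list(vertices = as.integer(vertices), hemisphere = hemisphere,
                 area_mm2 = area, mean_prediction = mean_pred,
                 centroid_mm = centroid, rank = NA_integer_,
                 artifact_flag = FALSE),
            class = "lp_cluster")
}

#' @export
print.lp_cluster <- function(x, ...) {
  cat(sprintf(
    "<cluster: %s, %d vertices, %.1f mm^2, mean score %.3f, rank %s>\n",
    x$hemisphere, length(x$vertices), x$area_mm2, x$mean_prediction,
    ifelse(is.na(x$rank), "-", x$rank)))
  invisible(x)
}

#' Extract suprathreshold clusters from per-vertex scores
#'
#' Connected components (triangle-edge adjacency) of the vertex set with
#' `score > threshold` (strict). Component area is the sum of member
#' vertex areas; components smaller than `min_area_mm2` are discarded as
#' noise.
#'
#' @param surface a [hemi_surface()].
#' @param scores per-vertex scores aligned to the surface.
#' @param threshold decision threshold (vertices strictly above enter).
#' @param min_area_mm2 minimum cluster area (default 50 mm^2).
#' @param areas optional precomputed [vertex_areas()] values.
#' @return list of `lp_cluster` (possibly empty), unranked.
#' @export
extract_clusters <- function(surface, scores, threshold,
                             min_area_mm2 = 50, areas = NULL) {
  scores <- overlay_values(scores)
  check_overlay_length(scores, surface)
  if (is.null(areas))
    areas <- overlay_values(suppressWarnings(vertex_areas(surface)))
  supra <- which(!is.na(scores) & scores > threshold)
  if (length(supra) == 0) return(list())
  ed <- mesh_edges(surface)
  keep <- ed$edges[, 1] %in% supra & ed$edges[, 2] %in% supra
  idx <- match(seq_len(n_vertices(surface)), supra)
  g <- igraph::graph_from_edgelist(
    cbind(idx[ed$edges[keep, 1]], idx[ed$edges[keep, 2]]),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(supra) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  out <- list()
  v <- surface$vertices
  for (cid in seq_len(max(comp))) {
    members <- supra[comp == cid]
    area <- sum(areas[members])
    if (area < min_area_mm2) next
    out[[length(out) + 1L]] <- new_cluster(
      members, surface$hemisphere, area, mean(scores[members]),
      colMeans(v[members, , drop = FALSE]))
  }
  out
}

#' Rank clusters by mean classifier prediction
#'
#' Descending mean prediction; ties broken by larger area, then left
#' hemisphere before right, then lower minimum vertex id. Rank 1 is the
#' strongest candidate. Ranking is invariant to input order.
#'
#' @param clusters list of `lp_cluster` (may span both hemispheres).
#' @return the same clusters, ordered, with `rank` filled in.
#' @export
rank_clusters <- function(clusters) {
  if (length(clusters) == 0) return(clusters)
  mp <- vapply(clusters, `[[`, numeric(1), "mean_prediction")
  ar <- vapply(clusters, `[[`, numeric(1), "area_mm2")
  hm <- vapply(clusters, `[[`, character(1), "hemisphere")
  mv <- vapply(clusters, function(cl) min(cl$vertices), integer(1))
  o <- order(-mp, -ar, match(hm, c("left", "right")), mv)
  clusters <- clusters[o]
  for (i in seq_along(clusters)) clusters[[i]]$rank <- i
  clusters
}

#' Does a cluster overlap a lesion mask?
#'
#' Overlap means at least one shared vertex; the mask must live on the
#' same hemisphere's vertex space as the cluster.
#'
#' @param cluster an `lp_cluster`.
#' @param mask binary overlay/vector (non-zero = in mask).
#' @return logical.
#' @export
overlap_with_mask <- function(cluster, mask) {
  m <- overlay_values(mask)
  any(m[cluster$vertices] > 0, na.rm = TRUE)
}

#' Export clusters as an integer label overlay
#'
#' @param clusters ranked or unranked `lp_cluster` list of one hemisphere.
#' @param surface the carrying [hemi_surface()].
#' @return integer [overlay()]: 0 outside clusters, cluster index inside.
#' @export
clusters_to_overlay <- function(clusters, surface) {
  lab <- integer(n_vertices(surface))
  for (i in seq_along(clusters)) lab[clusters[[i]]$vertices] <- i
  overlay(lab, name = "cluster_labels")
}

#' Cluster manifest table
#'
#' @param clusters list of `lp_cluster`.
#' @return data.frame with id, hemisphere, area, mean prediction, rank and
#'   centroid columns (one row per cluster).
#' @export
clusters_manifest <- function(clusters) {
  if (length(clusters) == 0)
    return(data.frame(id = integer(), hemisphere = character(),
                      area_mm2 = numeric(), mean_prediction = numeric(),
                      rank = integer(), centroid_x = numeric(),
                      centroid_y = numeric(), centroid_z = numeric()))
  data.frame(
    id = seq_along(clusters),
    hemisphere = vapply(clusters, `[[`, character(1), "hemisphere"),
    area_mm2 = vapply(clusters, `[[`, numeric(1), "area_mm2"),
    mean_prediction = vapply(clusters, `[[`, numeric(1),
                             "mean_prediction"),
    rank = vapply(clusters, `[[`, integer(1), "rank"),
    centroid_x = vapply(clusters, function(cl) cl$centroid_mm[1],
                        numeric(1)),
    centroid_y = vapply(clusters, function(cl) cl$centroid_mm[2],
                        numeric(1)),
    centroid_z = vapply(clusters, function(cl) cl$centroid_mm[3],
                        numeric(1)))
}
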