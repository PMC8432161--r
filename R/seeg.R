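# Relating predicted clusters to implanted sEEG electrode contacts.

#' Transform electrode contacts into surface space
#'
#' @param contacts an `electrode_set`.
#' @param affine an [affine_transform()] mapping contact space to surface
#'   space.
#' @return the contacts with transformed coordinates (labels preserved).
#' @export
transform_contacts <- function(contacts, affine) {
  xyz <- apply_affine(affine, as.matrix(contacts[, c("x", "y", "z")]))
  contacts$x <- xyz[, 1]; contacts$y <- xyz[, 2]; contacts$z <- xyz[, 3]
  contacts
}

#' Minimum Euclidean distance from a cluster to a contact
#'
#' Minimum over the cluster's member vertices of the Euclidean distance to
#' the contact coordinate. Vertex coordinates are taken from `surface`
#' (use the mid-thickness surface when gray and white are available).
#'
#' @param cluster an `lp_cluster` (non-empty).
#' @param surface the [hemi_surface()] carrying the cluster.
#' @param contact numeric length-3 coordinate (mm).
#' @return distance in mm.
#' @export
cluster_contact_distance <- function(cluster, surface, contact) {
  if (length(cluster$vertices) == 0) stop("empty cluster")
  v <- surface$vertices[cluster$vertices, , drop = FALSE]
  sqrt(min(rowSums(sweep(v, 2, as.numeric(contact))^2)))
}

#' Assess colocalization between clusters and SOZ contacts
#'
#' Computes, for every cluster, the minimum distance to each contact class
#' (SOZ / irritative / uninvolved). The patient is colocalized when some
#' (cluster, SOZ contact) pair lies strictly below `threshold_mm`.
#'
#' @param clusters list of `lp_cluster` (both hemispheres together).
#' @param contacts an `electrode_set` in surface space.
#' @param surfaces named list of [hemi_surface()]s (`left`, `right`)
#'   carrying cluster coordinates.
#' @param threshold_mm colocalization distance threshold (default 10 mm,
#'   strict `<`).
#' @return object of class `concordance_result`: `colocalized` (TRUE /
#'   FALSE / `"not-applicable"` when no SOZ contact exists), `distances`
#'   (per cluster x class data.frame), `nearest` (cluster index, contact
#'   row, distance of the closest cluster-SOZ pair), `threshold_mm`.
#' @export
assess_colocalization <- function(clusters, contacts, surfaces,
                                  threshold_mm = 10) {
  classes <- CONTACT_LABELS
  n_soz <- sum(contacts$label == "SOZ")
  dist_rows <- list()
  nearest <- list(cluster = NA_integer_, contact = NA_integer_,
                  distance = Inf)
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    surf <- surfaces[[cl$hemisphere]]
    for (lab in classes) {
      rows <- which(contacts$label == lab)
      if (length(rows) == 0) {
        dmin <- NA_real_; jmin <- NA_integer_
      } else {
        d <- vapply(rows, function(j) cluster_contact_distance(
          cl, surf, as.numeric(contacts[j, c("x", "y", "z")])),
          numeric(1))
        jmin <- rows[which.min(d)]; dmin <- min(d)
        if (lab == "SOZ" && dmin < nearest$distance)
          nearest <- list(cluster = i, contact = jmin, distance = dmin)
      }
      dist_rows[[length(dist_rows) + 1L]] <- data.frame(
        cluster = i, label = lab, min_distance_mm = dmin,
        nearest_contact = jmin)
    }
  }
  distances <- if (length(dist_rows)) do.call(rbind, dist_rows) else
    data.frame(cluster = integer(), label = character(),
               min_distance_mm = numeric(), nearest_contact = integer())
  colocalized <- if (n_soz == 0) "not-applicable" else
    is.finite(nearest$distance) && nearest$distance < threshold_mm
  structure(list(colocalized = colocalized, distances = distances,
                 nearest = nearest, threshold_mm = threshold_mm),
            class = "concordance_result")
}

#' Patient-level concordance classification
#'
#' Concordance between automated clusters and the sEEG result is defined
#' only for focal cortical seizure onset; mesial temporal, diffuse and
#' likely-focal (unlocalized) outcomes are `not-applicable` because the
#' cortical classifier cannot address them.
#'
#' @param concordance a `concordance_result` (or logical colocalization).
#' @param seeg_outcome one of `"focal"`, `"mTLE"`, `"diffuse"`,
#'   `"likely-focal"`.
#' @return `"yes"`, `"no"` or `"not-applicable"`.
#' @export
classify_patient <- function(concordance, seeg_outcome) {
  seeg_outcome <- match.arg(seeg_outcome, OUTCOME_LEVELS)
  if (seeg_outcome != "focal") return("not-applicable")
  coloc <- if (inherits(concordance, "concordance_result"))
    concordance$colocalized else concordance
  if (isTRUE(coloc)) "yes" else "no"
}
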