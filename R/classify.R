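#' Phase centroids on the PC1-PC2 plane
#'
#' Arithmetic mean of the member wells' scores per compound, concentration
#' and phase.
#'
#' @param scores Data frame from [project_pca()].
#' @return Data frame `compound`, `concentration`, `unit`, `phase`, `PC1`,
#'   `PC2`, `n_wells`.
#' @export
phase_centroids <- function(scores) {
  stopifnot(all(c("compound", "concentration", "phase", "PC1", "PC2") %in%
                  names(scores)))
  key <- interaction(scores$compound, scores$concentration, scores$phase,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(scores, key), function(g)
    data.frame(compound = g$compound[1L], concentration = g$concentration[1L],
               unit = g$unit[1L], phase = g$phase[1L],
               PC1 = mean(g$PC1), PC2 = mean(g$PC2), n_wells = nrow(g),
               stringsAsFactors = FALSE)))
  out <- out[order(out$compound, out$concentration, out$phase), ]
  rownames(out) <- NULL
  out
}

#' Distance between before- and after-chronic centroids
#'
#' Euclidean distance on the PC1-PC2 plane between two centroids of the same
#' compound at the same concentration in different phases.
#'
#' @param before,after Single-row centroid data frames ([phase_centroids()]
#'   rows).
#' @return Non-negative distance.
#' @export
chronic_shift_distance <- function(before, after) {
  if (before$compound != after$compound ||
      before$concentration != after$concentration) {
    stop("centroids must share compound and concentration")
  }
  if (before$phase == after$phase) stop("centroids must differ in phase")
  sqrt((before$PC1 - after$PC1)^2 + (before$PC2 - after$PC2)^2)
}

#' Vehicle-based detection threshold
#'
#' `k` times the sample SD of the vehicle's concentration-level centroid
#' distances (default k = 2, the "2SD of DMSO" rule). A zero SD yields a zero
#' threshold with a prominent warning, since every nonzero shift would then
#' be called.
#'
#' @param dmso_distances Numeric vector of vehicle distances (>= 2).
#' @param k SD multiplier (default 2).
#' @return Threshold in PC-plane units.
#' @export
dmso_threshold <- function(dmso_distances, k = 2) {
  stopifnot(length(dmso_distances) >= 2L, k > 0)
  s <- stats::sd(dmso_distances)
  if (s == 0) {
    warning("vehicle distances have zero SD: threshold is 0 and every ",
            "nonzero shift will be called addiction-like")
  }
  k * s
}

#' Classify chronic centroid shifts as addiction-like
#'
#' Projects the normalized features with the selected PCA model, computes the
#' before/after-chronic centroid distance per compound and concentration,
#' derives the threshold as `k` SD of the vehicle's distances, and flags
#' every distance above threshold. A compound is called addiction-like when
#' at least one of its concentrations is flagged; the lowest flagged
#' concentration is reported, and non-monotone flag patterns (a positive dose
#' below a negative one) are marked.
#'
#' @param features Normalized `mea_features` table with both phases.
#' @param model Selected `mea_pca` model.
#' @param design A [compound_design()].
#' @param k Vehicle SD multiplier (default 2).
#' @return A `shift_classification` list: `detections` (per compound x
#'   concentration), `compounds` (per-compound call), `threshold`,
#'   `vehicle_distances`, `centroids`, `scores`.
#' @export
classify_shifts <- function(features, model, design, k = 2) {
  stopifnot(inherits(model, "mea_pca"), inherits(design, "compound_design"))
  if (!isTRUE(attr(features, "normalized"))) {
    features <- normalize_to_vehicle(features)
  }
  scores <- project_pca(model, features)
  cent <- phase_centroids(scores)
  key <- interaction(cent$compound, cent$concentration, drop = TRUE)
  det <- do.call(rbind, lapply(split(cent, key), function(g) {
    if (nrow(g) != 2L) {
      message("classify_shifts: skipping ", g$compound[1L], " @ ",
              g$concentration[1L], g$unit[1L], " (missing phase)")
      return(NULL)
    }
    b <- g[g$phase == "before_chronic", ]
    a <- g[g$phase == "after_chronic", ]
    data.frame(compound = g$compound[1L],
               concentration = g$concentration[1L], unit = g$unit[1L],
               distance = chronic_shift_distance(b, a),
               stringsAsFactors = FALSE)
  }))
  det <- det[order(match(det$compound, design$compound), det$concentration), ]
  rownames(det) <- NULL
  vehicle <- design$compound[design$role == "vehicle"]
  vd <- det$distance[det$compound == vehicle]
  if (length(vd) < 2L) {
    stop("need >= 2 vehicle concentration-level distances for the threshold")
  }
  thr <- dmso_threshold(vd, k)
  det$threshold <- thr
  det$addiction_like <- det$distance > thr
  cmps <- unique(det$compound)
  comp <- do.call(rbind, lapply(cmps, function(cm) {
    d <- det[det$compound == cm, ]
    d <- d[order(d$concentration), ]
    pos <- which(d$addiction_like)
    lowest <- if (length(pos)) d$concentration[pos[1L]] else NA_real_
    monotone <- !length(pos) ||
      identical(pos, seq.int(pos[1L], nrow(d)))
    data.frame(compound = cm, role = design$role[design$compound == cm],
               addiction_like = length(pos) > 0L,
               n_positive = length(pos),
               lowest_positive_concentration = lowest,
               unit = d$unit[1L], monotone = monotone,
               stringsAsFactors = FALSE)
  }))
  rownames(comp) <- NULL
  structure(list(detections = det, compounds = comp, threshold = thr,
                 vehicle_distances = vd, centroids = cent, scores = scores,
                 k = k, vehicle = vehicle),
            class = "shift_classification")
}

#' @export
print.shift_classification <- function(x, ...) {
  cat(sprintf("Chronic-shift classification (threshold = %.4g = %g x SD of %s distances)\n",
              x$threshold, x$k, x$vehicle))
  for (i in seq_len(nrow(x$compounds))) {
    r <- x$compounds[i, ]
    cat(sprintf("  %-16s [%s]  %s", r$compound, r$role,
                if (r$addiction_like) "ADDICTION-LIKE" else "no response"))
    if (r$addiction_like) {
      cat(sprintf("  (%g %s or higher%s)", r$lowest_positive_concentration,
                  r$unit, if (r$monotone) "" else "; non-monotone pattern"))
    }
    cat("\n")
  }
  invisible(x)
}

#' Write classification outputs
#'
#' `detections.csv` (per compound x concentration distances, threshold and
#' flags) and `distances.csv` (the same distances in long form) with
#' deterministic formatting, so identical inputs give byte-identical files.
#'
#' @param cls A `shift_classification`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_classification <- function(cls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  det <- cls$detections
  det$distance <- sprintf("%.10g", det$distance)
  det$threshold <- sprintf("%.10g", det$threshold)
  utils::write.csv(det, file.path(dir, "detections.csv"), row.names = FALSE)
  utils::write.csv(det[, c("compound", "concentration", "unit", "distance")],
                   file.path(dir, "distances.csv"), row.names = FALSE)
  utils::write.csv(cls$compounds, file.path(dir, "compound_calls.csv"),
                   row.names = FALSE)
  invisible(dir)
}
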