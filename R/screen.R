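#' Fit the MEA addiction-liability screen
#'
#' The whole analysis in one call: vehicle-normalize the 13-parameter feature
#' table, exhaustively search all parameter subsets of size >= `min_size` for
#' a set on which only the addictive reference compounds shift between the
#' before- and after-chronic phases on PC1/PC2 (two-group MANOVA at level
#' `alpha`), select the most significant qualifying set, refit its PCA, and
#' classify every compound x concentration centroid shift against the
#' vehicle's `k`-SD distance threshold.
#'
#' @param features An `mea_features` table (raw or normalized) from
#'   [extract_features()] or [simulate_study_features()].
#' @param design A [compound_design()] labelling each compound.
#' @param alpha Significance level of the subset-qualification tests
#'   (default 0.05).
#' @param min_size Smallest subset size searched (default 2).
#' @param k Vehicle SD multiplier for the detection threshold (default 2).
#' @return An `addiction_screen` object with components `features`
#'   (normalized), `design`, `search`, `selection` (chosen subset + score),
#'   `model` (`mea_pca` or NULL), and `classification`
#'   (`shift_classification` or NULL when no subset qualifies).
#' @seealso [search_subsets()], [select_parameter_set()], [classify_shifts()]
#' @export
addiction_screen <- function(features, design, alpha = 0.05, min_size = 2,
                             k = 2) {
  stopifnot(inherits(features, "mea_features"),
            inherits(design, "compound_design"))
  if (!isTRUE(attr(features, "normalized"))) {
    features <- normalize_to_vehicle(features)
  }
  extra <- setdiff(unique(features$compound), design$compound)
  if (length(extra)) {
    stop("compounds missing from design: ", paste(extra, collapse = ", "))
  }
  search <- search_subsets(features, design, alpha = alpha,
                           min_size = min_size)
  sel <- select_parameter_set(search, features)
  cls <- if (sel$found) {
    classify_shifts(features, sel$model, design, k = k)
  }
  structure(list(features = features, design = design, search = search,
                 selection = sel, model = sel$model, classification = cls,
                 alpha = alpha, k = k),
            class = "addiction_screen")
}

#' @export
print.addiction_screen <- function(x, ...) {
  nq <- sum(x$search$evaluations$qualifies)
  cat(sprintf("MEA addiction screen: %d subsets searched, %d qualifying\n",
              nrow(x$search$evaluations), nq))
  if (!x$selection$found) {
    cat("No discriminating parameter set found.\n")
    return(invisible(x))
  }
  cat("Selected parameter set:", paste(x$selection$subset, collapse = ", "),
      sprintf("(score = %.3g)\n", x$selection$score))
  evr <- x$model$explained_variance_ratio
  cat(sprintf("PC1 %.1f%%, PC2 %.1f%% of variance (cumulative %.1f%%)\n",
              evr[1L], evr[2L], evr[1L] + evr[2L]))
  print(x$classification)
  invisible(x)
}

#' @export
summary.addiction_screen <- function(object, ...) {
  out <- list(
    n_subsets = nrow(object$search$evaluations),
    n_qualifying = sum(object$search$evaluations$qualifies),
    found = object$selection$found,
    subset = object$selection$subset,
    score = object$selection$score,
    explained_variance_ratio =
      if (object$selection$found) object$model$explained_variance_ratio,
    threshold = if (!is.null(object$classification))
      object$classification$threshold,
    compounds = if (!is.null(object$classification))
      object$classification$compounds)
  class(out) <- "summary.addiction_screen"
  out
}

#' @export
print.summary.addiction_screen <- function(x, ...) {
  cat(sprintf("Subsets searched: %d (%d qualifying)\n", x$n_subsets,
              x$n_qualifying))
  if (!x$found) {
    cat("No discriminating parameter set found.\n")
    return(invisible(x))
  }
  cat("Selected set:", paste(x$subset, collapse = ", "), "\n")
  cat(sprintf("Threshold: %.4g\n", x$threshold))
  print(x$compounds)
  invisible(x)
}

#' Component loadings of the selected model
#'
#' @param object An `addiction_screen`.
#' @param ... Unused.
#' @return Loadings matrix (parameter x component) or NULL.
#' @export
coef.addiction_screen <- function(object, ...) {
  if (is.null(object$model)) NULL else object$model$loadings
}

#' Project new feature rows with the fitted screen
#'
#' @param object An `addiction_screen` with a selected model.
#' @param newdata An `mea_features` table (raw or normalized). Defaults to
#'   the training features.
#' @param ... Unused.
#' @return Data frame of PC scores (see [project_pca()]).
#' @export
predict.addiction_screen <- function(object, newdata = NULL, ...) {
  if (is.null(object$model)) stop("no discriminating set was found")
  if (is.null(newdata)) newdata <- object$features
  if (!isTRUE(attr(newdata, "normalized"))) {
    newdata <- normalize_to_vehicle(newdata)
  }
  project_pca(object$model, newdata)
}

#' Plot an addiction screen
#'
#' `which = "pca"` draws the per-compound phase centroids on the PC1-PC2
#' plane (circles before, squares after chronic administration, lines joining
#' the paired centroids). `which = "distances"` draws the per-concentration
#' centroid distances with the vehicle threshold line.
#'
#' @param x An `addiction_screen` with a classification.
#' @param which `"pca"` or `"distances"`.
#' @param ... Passed to the underlying plot call.
#' @export
plot.addiction_screen <- function(x, which = c("pca", "distances"), ...) {
  which <- match.arg(which)
  if (is.null(x$classification)) stop("nothing to plot: no qualifying subset")
  cent <- x$classification$centroids
  cmps <- unique(cent$compound)
  cols <- grDevices::hcl.colors(max(3L, length(cmps)), "Dark 3")
  if (which == "pca") {
    plot(cent$PC1, cent$PC2, type = "n",
         xlab = sprintf("PC1 (%.1f%%)", x$model$explained_variance_ratio[1L]),
         ylab = sprintf("PC2 (%.1f%%)", x$model$explained_variance_ratio[2L]),
         main = "Phase centroids on the selected parameter set", ...)
    for (i in seq_along(cmps)) {
      g <- cent[cent$compound == cmps[i], ]
      for (cc in unique(g$concentration)) {
        gg <- g[g$concentration == cc, ]
        if (nrow(gg) == 2L) {
          graphics::lines(gg$PC1, gg$PC2, col = cols[i])
        }
      }
      before <- g$phase == "before_chronic"
      graphics::points(g$PC1[before], g$PC2[before], pch = 1, col = cols[i])
      graphics::points(g$PC1[!before], g$PC2[!before], pch = 15,
                       col = cols[i])
    }
    graphics::legend("topright", legend = cmps, col = cols[seq_along(cmps)],
                     pch = 15, cex = 0.7, bty = "n")
  } else {
    det <- x$classification$detections
    det$label <- sprintf("%s %g", det$compound, det$concentration)
    bp <- graphics::barplot(det$distance, names.arg = det$label, las = 2,
                            cex.names = 0.55,
                            col = ifelse(det$addiction_like, "firebrick",
                                         "grey70"),
                            ylab = "centroid shift distance", ...)
    graphics::abline(h = x$classification$threshold, lty = 2)
    invisible(bp)
  }
}

#' Group-mean heatmap data with Dunnett significance flags
#'
#' Per compound, phase and parameter: the mean normalized value at each
#' concentration and the Dunnett-adjusted p-value of that concentration
#' against the well-matched vehicle baseline values (the concentration-0
#' recordings of the same wells). This is the tabular analogue of the
#' screening heatmaps.
#'
#' @param features Normalized `mea_features`.
#' @param alpha Significance level for the `significant` flag.
#' @return Data frame `compound`, `phase`, `parameter`, `concentration`,
#'   `mean`, `adjusted_p`, `significant`.
#' @export
feature_heatmap_data <- function(features, alpha = 0.05) {
  if (!isTRUE(attr(features, "normalized"))) {
    features <- normalize_to_vehicle(features)
  }
  pars <- mea_parameters()
  out <- list()
  for (cm in unique(features$compound)) {
    for (ph in unique(features$phase)) {
      d <- features[features$compound == cm & features$phase == ph, ]
      concs <- sort(unique(d$concentration[d$concentration > 0]))
      for (par in pars) {
        ctrl <- d[d$concentration == 0, par]
        trt <- lapply(concs, function(cc) d[d$concentration == cc, par])
        trt <- lapply(trt, function(v) v[!is.na(v)])
        padj <- rep(NA_real_, length(concs))
        usable <- which(lengths(trt) >= 2L)
        if (length(usable) && length(ctrl[!is.na(ctrl)]) >= 2L &&
            stats::var(unlist(c(list(ctrl[!is.na(ctrl)]), trt[usable]))) > 0) {
          dt <- dunnett_test(ctrl[!is.na(ctrl)], trt[usable], alpha = alpha)
          padj[usable] <- dt$comparisons$adjusted_p
        }
        out[[length(out) + 1L]] <- data.frame(
          compound = cm, phase = ph, parameter = par, concentration = concs,
          mean = vapply(trt, function(v) if (length(v)) mean(v) else
            NA_real_, numeric(1)),
          adjusted_p = padj, significant = !is.na(padj) & padj < alpha,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
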