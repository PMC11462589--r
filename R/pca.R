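#' Enumerate parameter subsets
#'
#' All subsets of `n_parameters` parameters with at least `min_size` members,
#' in deterministic order (increasing size, lexicographic within size). For
#' `min_size = 2` the count is the closed form `2^n - 1 - n`; for the 13
#' analytical parameters that is 8178 candidate sets.
#'
#' @param n_parameters Number of parameters (default 13).
#' @param min_size Smallest subset size (default 2).
#' @return List of integer index vectors.
#' @export
enumerate_subsets <- function(n_parameters = 13, min_size = 2) {
  stopifnot(min_size >= 1)
  if (min_size > n_parameters) {
    warning("min_size exceeds n_parameters; no subsets")
    return(list())
  }
  out <- list()
  for (k in min_size:n_parameters) {
    out <- c(out, utils::combn(n_parameters, k, simplify = FALSE))
  }
  out
}

#' Fit a standardized PCA on a parameter subset
#'
#' Rows with a missing value in any subset column are dropped; the remaining
#' columns are z-scored (the 13 parameters have incommensurate units) and the
#' principal components come from the eigendecomposition of the correlation
#' matrix. Components are ordered by decreasing variance and carry a fixed
#' sign convention: the largest-magnitude loading of each component is
#' positive, so projections are reproducible across fits.
#'
#' @param features A normalized `mea_features` table.
#' @param subset Character vector of parameter names (>= 2) from
#'   [mea_parameters()].
#' @param rows Optional logical/integer row filter applied before fitting
#'   (default: all dose rows, `concentration > 0`).
#' @return An `mea_pca` model: `subset`, `center`, `scale`, `loadings`
#'   (parameter x component), `explained_variance_ratio` (percent, sums
#'   to 100), `n_rows`.
#' @export
fit_pca <- function(features, subset, rows = NULL) {
  stopifnot(inherits(features, "mea_features"), length(subset) >= 2L,
            all(subset %in% mea_parameters()))
  if (is.null(rows)) rows <- features$concentration > 0
  X <- as.matrix(features[rows, subset, drop = FALSE])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 3L) stop("need at least 3 complete rows to fit a PCA")
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  if (any(scl == 0)) {
    stop("constant parameter column(s): ",
         paste(subset[scl == 0], collapse = ", "))
  }
  Z <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  e <- eigen(crossprod(Z) / (nrow(Z) - 1L), symmetric = TRUE)
  V <- .fix_signs(e$vectors)
  ev <- pmax(e$values, 0)
  dimnames(V) <- list(subset, paste0("PC", seq_along(ev)))
  structure(list(subset = subset, center = ctr, scale = scl, loadings = V,
                 explained_variance_ratio = 100 * ev / sum(ev),
                 n_rows = nrow(X)),
            class = "mea_pca")
}

# make the largest-|loading| entry of each component positive
.fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' @export
print.mea_pca <- function(x, ...) {
  cat("<mea_pca> parameters:", paste(x$subset, collapse = ", "), "\n")
  cat("explained variance (%):",
      paste(sprintf("%.1f", x$explained_variance_ratio), collapse = ", "),
      sprintf(" (n = %d rows)\n", x$n_rows))
  invisible(x)
}

#' Project feature rows onto a fitted PCA
#'
#' Scores are `t(loadings) %*% ((x - center) / scale)`. Rows missing any
#' subset parameter are dropped with a message; an error is raised if nothing
#' remains.
#'
#' @param model An `mea_pca` from [fit_pca()].
#' @param features A normalized `mea_features` table.
#' @param rows Optional row filter (default: dose rows).
#' @param n_components Number of score columns to keep (default 2).
#' @return Data frame with the metadata columns and `PC1`, `PC2`, ...
#' @export
project_pca <- function(model, features, rows = NULL, n_components = 2) {
  stopifnot(inherits(model, "mea_pca"), inherits(features, "mea_features"),
            all(model$subset %in% names(features)))
  if (is.null(rows)) rows <- features$concentration > 0
  dat <- features[rows, , drop = FALSE]
  X <- as.matrix(dat[, model$subset, drop = FALSE])
  ok <- stats::complete.cases(X)
  if (!any(ok)) stop("no rows with complete subset values to project")
  if (any(!ok)) {
    message("project_pca: dropped ", sum(!ok),
            " row(s) with missing subset values")
  }
  Z <- sweep(sweep(X[ok, , drop = FALSE], 2L, model$center), 2L,
             model$scale, "/")
  k <- min(n_components, ncol(model$loadings))
  S <- Z %*% model$loadings[, seq_len(k), drop = FALSE]
  cbind(dat[ok, c("well", "compound", "concentration", "unit", "phase")],
        as.data.frame(S))
}

#' Save / load a fitted PCA model as JSON
#'
#' @param model An `mea_pca`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_pca_model()` returns the model.
#' @export
write_pca_model <- function(model, path) {
  stopifnot(inherits(model, "mea_pca"))
  obj <- list(subset = model$subset, center = unname(model$center),
              scale = unname(model$scale),
              loadings = unname(model$loadings),
              explained_variance_ratio =
                unname(model$explained_variance_ratio),
              n_rows = model$n_rows)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  L <- as.matrix(obj$loadings)
  dimnames(L) <- list(obj$subset, paste0("PC", seq_len(ncol(L))))
  structure(list(subset = obj$subset,
                 center = stats::setNames(obj$center, obj$subset),
                 scale = stats::setNames(obj$scale, obj$subset),
                 loadings = L,
                 explained_variance_ratio = obj$explained_variance_ratio,
                 n_rows = obj$n_rows),
            class = "mea_pca")
}
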