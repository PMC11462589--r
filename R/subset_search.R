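#' Study design: compound roles
#'
#' The subset search and classifier need to know which compounds carry an
#' addictive reference profile, which are non-addictive references, and which
#' one is the vehicle (solvent) control.
#'
#' @param compound Character vector of compound names.
#' @param role Matching vector with values `"addictive"`, `"non_addictive"`
#'   or `"vehicle"` (exactly one vehicle).
#' @return A `compound_design` data frame.
#' @export
compound_design <- function(compound, role) {
  role <- match.arg(role, c("addictive", "non_addictive", "vehicle"),
                    several.ok = TRUE)
  stopifnot(length(compound) == length(role), sum(role == "vehicle") == 1L)
  structure(data.frame(compound = compound, role = role,
                       stringsAsFactors = FALSE),
            class = c("compound_design", "data.frame"))
}

# fast two-group Hotelling p on 2-D scores (no validation; hot path)
.hotelling_p <- function(sa, sb) {
  n1 <- nrow(sa)
  n2 <- nrow(sb)
  d1 <- colMeans(sa)
  d2 <- colMeans(sb)
  d <- d1 - d2
  A <- crossprod(sa) - n1 * tcrossprod(d1)
  B <- crossprod(sb) - n2 * tcrossprod(d2)
  S <- (A + B) / (n1 + n2 - 2)
  det_s <- S[1, 1] * S[2, 2] - S[1, 2]^2
  if (!is.finite(det_s) || det_s <= 0) {
    S <- S + diag(2) * 1e-8 * max(mean(diag(S)), .Machine$double.xmin)
    det_s <- S[1, 1] * S[2, 2] - S[1, 2]^2
  }
  Sinv_d <- c(S[2, 2] * d[1] - S[1, 2] * d[2],
              S[1, 1] * d[2] - S[1, 2] * d[1]) / det_s
  T2 <- (n1 * n2 / (n1 + n2)) * sum(d * Sinv_d)
  df2 <- n1 + n2 - 3
  stats::pf(T2 * df2 / ((n1 + n2 - 2) * 2), 2, df2, lower.tail = FALSE)
}

#' Exhaustive subset search for an addiction-discriminating parameter set
#'
#' For every parameter subset of size >= `min_size`, fits a standardized PCA
#' on all well-level normalized dose rows (all compounds pooled), projects
#' onto PC1/PC2, and tests each reference compound for a before- versus
#' after-chronic shift with a two-group MANOVA (Hotelling T-squared) pooling
#' all concentrations. A subset qualifies when every addictive compound
#' shifts significantly (p < `alpha`) while no non-addictive compound does
#' (p >= `alpha`). The selection score of a qualifying subset is the largest
#' phase-test p among the addictive compounds (smaller = more significant).
#'
#' A compound with fewer than 3 complete rows in either phase cannot be
#' tested; such subsets are disqualified. The search is deterministic: no
#' randomness anywhere.
#'
#' @param features Normalized `mea_features` table.
#' @param design A [compound_design()].
#' @param alpha Significance level (default 0.05).
#' @param min_size Smallest subset size (default 2).
#' @param early_exit Stop evaluating a subset at the first disqualifying
#'   compound (default TRUE; per-compound p for untested compounds is `NA`).
#' @return A `subset_search` object: `evaluations` data frame (`subset`,
#'   `size`, `qualifies`, `score`), matrix `p` (subset x test compound),
#'   `alpha`, and the parameter names searched.
#' @export
search_subsets <- function(features, design, alpha = 0.05, min_size = 2,
                           early_exit = TRUE) {
  stopifnot(inherits(features, "mea_features"),
            inherits(design, "compound_design"))
  if (!isTRUE(attr(features, "normalized"))) {
    features <- normalize_to_vehicle(features)
  }
  pars <- mea_parameters()
  dose <- features$concentration > 0
  dat <- features[dose, , drop = FALSE]
  X <- as.matrix(dat[, pars])
  NAmat <- is.na(X)
  X0 <- X
  X0[NAmat] <- 0
  # addictive compounds first: most subsets fail there, so early exit is cheap
  test_cmp <- design$compound[design$role != "vehicle"]
  test_role <- design$role[match(test_cmp, design$compound)]
  ord <- order(test_role != "addictive")
  test_cmp <- test_cmp[ord]
  test_role <- test_role[ord]
  is_before <- dat$phase == "before_chronic"
  cmp_rows <- lapply(test_cmp, function(cm) {
    i <- dat$compound == cm
    list(before = which(i & is_before), after = which(i & !is_before))
  })
  subsets <- enumerate_subsets(length(pars), min_size)
  ns <- length(subsets)
  pmat <- matrix(NA_real_, ns, length(test_cmp),
                 dimnames = list(NULL, test_cmp))
  qualifies <- logical(ns)
  score <- rep(NA_real_, ns)
  for (s in seq_len(ns)) {
    idx <- subsets[[s]]
    k <- length(idx)
    ok <- rowSums(NAmat[, idx, drop = FALSE]) == 0L
    pos <- cumsum(ok)             # global row -> row within complete set
    enough <- all(vapply(cmp_rows, function(cr)
      sum(ok[cr$before]) >= 3L && sum(ok[cr$after]) >= 3L, logical(1)))
    if (!enough) next
    Z <- X0[ok, idx, drop = FALSE]
    ctr <- colMeans(Z)
    Z <- sweep(Z, 2L, ctr)
    scl <- sqrt(colSums(Z^2) / (nrow(Z) - 1L))
    if (any(scl == 0)) next
    Z <- sweep(Z, 2L, scl, "/")
    e <- eigen(crossprod(Z) / (nrow(Z) - 1L), symmetric = TRUE)
    V <- .fix_signs(e$vectors[, 1:2, drop = FALSE])
    S <- Z %*% V
    all_ok <- TRUE
    max_addictive_p <- 0
    for (j in seq_along(test_cmp)) {
      cr <- cmp_rows[[j]]
      sa <- S[pos[cr$before[ok[cr$before]]], , drop = FALSE]
      sb <- S[pos[cr$after[ok[cr$after]]], , drop = FALSE]
      p <- .hotelling_p(sa, sb)
      pmat[s, j] <- p
      if (test_role[j] == "addictive") {
        if (p >= alpha) {
          all_ok <- FALSE
        } else {
          max_addictive_p <- max(max_addictive_p, p)
        }
      } else if (p < alpha) {
        all_ok <- FALSE
      }
      if (!all_ok && early_exit) break
    }
    if (all_ok) {
      qualifies[s] <- TRUE
      score[s] <- max_addictive_p
    }
  }
  ev <- data.frame(
    subset = vapply(subsets, function(i) paste(pars[i], collapse = "+"),
                    character(1)),
    size = lengths(subsets), qualifies = qualifies, score = score,
    stringsAsFactors = FALSE)
  structure(list(evaluations = ev, p = pmat, subsets = subsets,
                 parameters = pars, alpha = alpha),
            class = "subset_search")
}

#' Evaluate one parameter subset
#'
#' Single-subset version of [search_subsets()] with full per-compound output.
#'
#' @param subset Character vector of parameter names.
#' @param features Normalized `mea_features` table.
#' @param design A [compound_design()].
#' @param alpha Significance level.
#' @return List: `subset`, `p` (named per test compound), `qualifies`,
#'   `score`.
#' @export
evaluate_subset <- function(subset, features, design, alpha = 0.05) {
  stopifnot(all(subset %in% mea_parameters()))
  if (!isTRUE(attr(features, "normalized"))) {
    features <- normalize_to_vehicle(features)
  }
  dat <- features[features$concentration > 0, , drop = FALSE]
  X <- as.matrix(dat[, subset, drop = FALSE])
  ok <- stats::complete.cases(X)
  model <- try(fit_pca(features, subset), silent = TRUE)
  if (inherits(model, "try-error")) {
    return(list(subset = subset, p = NULL, qualifies = FALSE,
                score = NA_real_,
                reason = attr(model, "condition")$message))
  }
  sc <- project_pca(model, features)
  test <- design[design$role != "vehicle", ]
  p <- stats::setNames(rep(NA_real_, nrow(test)), test$compound)
  for (cm in test$compound) {
    a <- sc[sc$compound == cm & sc$phase == "before_chronic",
            c("PC1", "PC2")]
    b <- sc[sc$compound == cm & sc$phase == "after_chronic",
            c("PC1", "PC2")]
    if (nrow(a) < 3L || nrow(b) < 3L) {
      return(list(subset = subset, p = p, qualifies = FALSE,
                  score = NA_real_,
                  reason = paste0("insufficient complete wells for ", cm)))
    }
    p[cm] <- manova_two_group(as.matrix(a), as.matrix(b))$p
  }
  addictive <- test$compound[test$role == "addictive"]
  nonadd <- test$compound[test$role == "non_addictive"]
  qual <- all(p[addictive] < alpha) && all(p[nonadd] >= alpha)
  list(subset = subset, p = p, qualifies = qual,
       score = if (qual) max(p[addictive]) else NA_real_)
}

#' Select the most significant qualifying parameter set
#'
#' Among qualifying subsets, picks the one with the smallest selection score
#' (ties broken by smaller size, then lexicographically) and refits its PCA
#' model for reuse by the classifier. When nothing qualifies an explicit
#' no-discriminating-set result is returned, not an error.
#'
#' @param search A `subset_search` from [search_subsets()].
#' @param features The normalized `mea_features` the search ran on.
#' @return List with `found` (logical), `subset` (character), `score`, and
#'   fitted `model` (`mea_pca`), or `found = FALSE`.
#' @export
select_parameter_set <- function(search, features) {
  stopifnot(inherits(search, "subset_search"))
  ev <- search$evaluations
  q <- which(ev$qualifies)
  if (!length(q)) {
    return(list(found = FALSE, subset = character(0), score = NA_real_,
                model = NULL))
  }
  q <- q[order(ev$score[q], ev$size[q], ev$subset[q])]
  best <- q[1L]
  subset <- search$parameters[search$subsets[[best]]]
  model <- fit_pca(features, subset)
  list(found = TRUE, subset = subset, score = ev$score[best], model = model,
       p = search$p[best, ])
}

#' Write the subset-search report as CSV
#'
#' One row per subset: the subset, whether it qualifies, its score, and the
#' per-compound phase-shift p-values (NA where the evaluation stopped early).
#'
#' @param search A `subset_search`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_search_report <- function(search, path) {
  out <- cbind(search$evaluations,
               stats::setNames(as.data.frame(search$p),
                               paste0("p_", colnames(search$p))))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
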