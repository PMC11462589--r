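#' One-way fixed-effects ANOVA
#'
#' Thin wrapper around the standard linear-model ANOVA for a list of numeric
#' samples. When every group has zero within-group variance the F statistic is
#' undefined; the degenerate convention is p = 0 if the group means differ and
#' p = 1 otherwise (with a warning).
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2).
#' @return List with elements `F` and `p`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(vapply(groups, length, integer(1)) >= 2L))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (all(vapply(groups, stats::var, numeric(1)) == 0)) {
    warning("zero within-group variance in every group")
    means <- vapply(groups, mean, numeric(1))
    return(list(F = NA_real_, p = if (stats::var(means) > 0) 0 else 1))
  }
  a <- stats::anova(stats::lm(y ~ g))
  list(F = a$`F value`[1L], p = a$`Pr(>F)`[1L])
}

#' Dunnett many-to-one comparisons against a control
#'
#' Classic two-sided, equal-variance Dunnett procedure: pooled-variance t
#' statistics for each treatment against the shared control, with
#' multiplicity-adjusted p-values from the equicoordinate probability of the
#' multivariate t distribution whose correlation comes from the group sizes
#' (`rho_ij = sqrt(n_i n_j / ((n_i + n0)(n_j + n0)))`). With a single
#' treatment it reduces to the two-sided pooled t-test.
#'
#' @param control Numeric vector of control observations (n >= 2).
#' @param treatments List of numeric treatment vectors (>= 1).
#' @param alpha Familywise significance level (default 0.05).
#' @param abseps Absolute tolerance for the multivariate-t probabilities
#'   (default 1e-4).
#' @return A `dunnett_result` list: data frame `comparisons` (mean difference,
#'   t, unadjusted and adjusted p, significance flag), global ANOVA `F` and
#'   `p`, `df`, and `alpha`.
#' @export
dunnett_test <- function(control, treatments, alpha = 0.05, abseps = 1e-4) {
  if (is.numeric(treatments)) treatments <- list(treatments)
  stopifnot(length(control) >= 2L, length(treatments) >= 1L)
  k <- length(treatments)
  n0 <- length(control)
  ni <- lengths(treatments)
  N <- n0 + sum(ni)
  df <- N - (k + 1L)
  groups <- c(list(control), treatments)
  ss <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  s2 <- ss / df
  mdiff <- vapply(treatments, mean, numeric(1)) - mean(control)
  se <- sqrt(s2 * (1 / ni + 1 / n0))
  tstat <- mdiff / se
  lam <- sqrt(ni / (ni + n0))
  R <- outer(lam, lam)
  diag(R) <- 1
  p_unadj <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p_adj <- vapply(abs(tstat), function(tq) {
    if (k == 1L) return(2 * stats::pt(tq, df, lower.tail = FALSE))
    1 - mvtnorm::pmvt(lower = rep(-tq, k), upper = rep(tq, k), df = df,
                      corr = R, algorithm = mvtnorm::GenzBretz(
                        abseps = abseps, maxpts = 50000L))[1L]
  }, numeric(1))
  p_adj <- pmin(1, pmax(p_adj, p_unadj))
  nm <- names(treatments)
  if (is.null(nm)) nm <- paste0("treatment", seq_len(k))
  aov_res <- one_way_anova(groups)
  structure(list(
    comparisons = data.frame(group = nm, mean_diff = mdiff, t = tstat,
                             p = p_unadj, adjusted_p = p_adj,
                             significant = p_adj < alpha),
    F = aov_res$F, p = aov_res$p, df = df, alpha = alpha),
    class = "dunnett_result")
}

#' @export
print.dunnett_result <- function(x, ...) {
  cat(sprintf("Dunnett many-to-one comparisons (two-sided, alpha = %g)\n",
              x$alpha))
  cat(sprintf("Global ANOVA: F = %.4g, p = %.4g (df error = %d)\n",
              x$F, x$p, x$df))
  print(x$comparisons, digits = 4)
  invisible(x)
}

#' Two-group multivariate test on 2-D scores
#'
#' Hotelling's T-squared for two independent groups of bivariate points (the
#' PC1/PC2 scores of the before- and after-chronic wells), reported together
#' with the equivalent Wilks' lambda and its exact F transformation - for two
#' groups the two statistics give the identical p-value. A singular pooled
#' covariance is regularized with a tiny ridge (1e-8 of the mean diagonal)
#' and flagged with a warning.
#'
#' @param scores_a,scores_b Numeric matrices (n x 2), n >= 3 each.
#' @return A `manova_result` list: `T2`, `wilks`, `F`, `df` (length 2), `p`.
#' @export
manova_two_group <- function(scores_a, scores_b) {
  scores_a <- as.matrix(scores_a)
  scores_b <- as.matrix(scores_b)
  stopifnot(ncol(scores_a) == 2L, ncol(scores_b) == 2L,
            nrow(scores_a) >= 3L, nrow(scores_b) >= 3L)
  n1 <- nrow(scores_a)
  n2 <- nrow(scores_b)
  d <- colMeans(scores_a) - colMeans(scores_b)
  S <- (crossprod(sweep(scores_a, 2, colMeans(scores_a))) +
        crossprod(sweep(scores_b, 2, colMeans(scores_b)))) / (n1 + n2 - 2)
  det_s <- S[1, 1] * S[2, 2] - S[1, 2]^2
  if (!is.finite(det_s) || det_s <= .Machine$double.eps * mean(diag(S))^2) {
    warning("singular pooled covariance; ridge regularization applied")
    S <- S + diag(2) * 1e-8 * max(mean(diag(S)), .Machine$double.xmin)
  }
  T2 <- (n1 * n2 / (n1 + n2)) * drop(d %*% solve(S, d))
  p_dim <- 2L
  df2 <- n1 + n2 - p_dim - 1L
  Fstat <- T2 * df2 / ((n1 + n2 - 2L) * p_dim)
  p <- stats::pf(Fstat, p_dim, df2, lower.tail = FALSE)
  structure(list(T2 = T2, wilks = 1 / (1 + T2 / (n1 + n2 - 2L)),
                 F = Fstat, df = c(p_dim, df2), p = p,
                 n = c(n1, n2)),
            class = "manova_result")
}

#' @export
print.manova_result <- function(x, ...) {
  cat(sprintf(
    "Two-group MANOVA on PC scores: T2 = %.4g, Wilks = %.4g, F(%d,%d) = %.4g, p = %.4g\n",
    x$T2, x$wilks, x$df[1L], x$df[2L], x$F, x$p))
  invisible(x)
}

#' Write test results as tidy CSV
#'
#' One row per comparison: `test,group,statistic,p,adjusted_p,significant`.
#'
#' @param result A `dunnett_result` or `manova_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_test_results <- function(result, path) {
  if (inherits(result, "dunnett_result")) {
    out <- data.frame(test = "dunnett", group = result$comparisons$group,
                      statistic = result$comparisons$t,
                      p = result$comparisons$p,
                      adjusted_p = result$comparisons$adjusted_p,
                      significant = result$comparisons$significant)
  } else if (inherits(result, "manova_result")) {
    out <- data.frame(test = "manova_two_group", group = "phase",
                      statistic = result$T2, p = result$p,
                      adjusted_p = result$p, significant = result$p < 0.05)
  } else {
    stop("unsupported result type")
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
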