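test_that("subset enumeration matches the closed form", {
  expect_length(enumerate_subsets(3, 2), 4L)
  expect_length(enumerate_subsets(2, 2), 1L)
  for (n in 2:16) {
    expect_length(enumerate_subsets(n, 2), 2^n - 1 - n)
  }
  expect_warning(empty <- enumerate_subsets(3, 5))
  expect_length(empty, 0L)
  # deterministic ordering
  expect_identical(enumerate_subsets(5, 2), enumerate_subsets(5, 2))
})

test_that("PCA fitting standardizes, orders and signs components", {
  pars <- mea_parameters()
  set.seed(8)
  n <- 4000
  base <- matrix(rnorm(n * 13, 100, 1e-9), ncol = 13,
                 dimnames = list(NULL, pars))
  tab <- cbind(data.frame(well = "w", compound = "x", concentration = 1,
                          unit = "uM", phase = "before_chronic"),
               as.data.frame(base))
  attr(tab, "normalized") <- TRUE
  class(tab) <- c("mea_features", "data.frame")

  # a single direction of variation: PC1 takes all of it
  tab$TS <- 100 + rnorm(n, 0, 5)
  tab$nNB <- tab$TS
  m2 <- fit_pca(tab, c("TS", "nNB"))
  expect_equal(m2$explained_variance_ratio[1], 100, tolerance = 1e-8)

  # isotropic data splits variance evenly
  tab$TS <- rnorm(n)
  tab$nNB <- rnorm(n)
  m3 <- fit_pca(tab, c("TS", "nNB"))
  expect_equal(m3$explained_variance_ratio[1], 50, tolerance = 3)
  expect_equal(sum(m3$explained_variance_ratio), 100, tolerance = 1e-9)

  # training projection is centred; sign convention holds
  sc <- project_pca(m3, tab)
  expect_lt(abs(mean(sc$PC1)), 1e-10)
  expect_lt(abs(mean(sc$PC2)), 1e-10)
  for (j in seq_len(ncol(m3$loadings))) {
    expect_gt(m3$loadings[which.max(abs(m3$loadings[, j])), j], 0)
  }

  tab$TS <- 5
  expect_error(fit_pca(tab, c("TS", "nNB")), "TS")
})

test_that("projection matches hand-computed scores and survives JSON", {
  m <- structure(list(
    subset = c("IBI", "Duration"),
    center = c(IBI = 100, Duration = 50),
    scale = c(IBI = 10, Duration = 5),
    loadings = matrix(c(1 / sqrt(2), 1 / sqrt(2), 1 / sqrt(2), -1 / sqrt(2)),
                      2, 2, dimnames = list(c("IBI", "Duration"),
                                            c("PC1", "PC2"))),
    explained_variance_ratio = c(60, 40), n_rows = 10), class = "mea_pca")
  row <- data.frame(well = "w", compound = "x", concentration = 1,
                    unit = "uM", phase = "before_chronic", IBI = 120,
                    Duration = 45)
  tab <- row
  for (p in setdiff(mea_parameters(), c("IBI", "Duration"))) tab[[p]] <- 1
  attr(tab, "normalized") <- TRUE
  class(tab) <- c("mea_features", "data.frame")
  sc <- project_pca(m, tab)
  z <- c((120 - 100) / 10, (45 - 50) / 5)
  expect_equal(sc$PC1, sum(z * m$loadings[, 1]), tolerance = 1e-12)
  expect_equal(sc$PC2, sum(z * m$loadings[, 2]), tolerance = 1e-12)
  # centre row scores to zero
  tab$IBI <- 100
  tab$Duration <- 50
  sc0 <- project_pca(m, tab)
  expect_equal(unlist(sc0[, c("PC1", "PC2")]), c(PC1 = 0, PC2 = 0))

  f <- withr::local_tempfile(fileext = ".json")
  write_pca_model(m, f)
  back <- read_pca_model(f)
  expect_equal(back$loadings, m$loadings, tolerance = 1e-12)
  expect_equal(back$center, m$center)
  expect_equal(back$scale, m$scale)
})

test_that("a planted timing shift makes the planted subset qualify", {
  fd <- feature_design()
  tab <- simulate_feature_table(fd, 424242)
  des <- feature_design_roles(fd)
  ev <- evaluate_subset(c("IBI", "Duration", "IMFI", "Duration_IQR"),
                        tab, des)
  expect_true(ev$qualifies)
  add <- des$compound[des$role == "addictive"]
  expect_true(all(ev$p[add] < 0.05))
  expect_true(all(ev$p[setdiff(names(ev$p), add)] >= 0.05))
})

test_that("a single huge planted contrast qualifies with a tiny p", {
  # one addictive and one non-addictive compound, massive phase shift
  fd <- feature_design(wells = 6)
  fd$compounds <- fd$compounds[c("NicotineLike", "NegativeControl",
                                 "VehicleControl")]
  fd$compounds$NicotineLike$chronic <- list(IBI = 6, IMFI = 6)
  tab <- simulate_feature_table(fd, 77)
  des <- feature_design_roles(fd)
  ev <- evaluate_subset(c("IBI", "IMFI"), tab, des)
  expect_true(ev$qualifies)
  expect_lt(ev$p["NicotineLike"], 1e-4)
})

test_that("without phase effects essentially no subset qualifies", {
  fd <- feature_design(timing_shift = 0)
  # switch off the chronic remodeling as well: a fully null study
  fd$compounds <- lapply(fd$compounds, function(cmp) {
    cmp$chronic <- list()
    cmp
  })
  des <- feature_design_roles(fd)
  frac <- vapply(1:8, function(r) {
    tab <- simulate_feature_table(fd, 600 + r)
    mean(search_subsets(tab, des)$evaluations$qualifies)
  }, numeric(1))
  # each subset needs all five addictive compounds significant at once;
  # under the null that has probability of the order alpha^5
  expect_lt(mean(frac), 1e-3)
})

test_that("selection orders by score then size and reports absence", {
  fd <- feature_design()
  tab <- simulate_feature_table(fd, 515151)
  des <- feature_design_roles(fd)
  s <- search_subsets(tab, des)
  sel <- select_parameter_set(s, tab)
  expect_true(sel$found)
  q <- which(s$evaluations$qualifies)
  expect_equal(sel$score, min(s$evaluations$score[q]))
  expect_s3_class(sel$model, "mea_pca")

  # determinism of the whole search
  s2 <- search_subsets(tab, des)
  expect_identical(s$evaluations, s2$evaluations)

  # no qualifying subset -> explicit result, not an error
  s$evaluations$qualifies[] <- FALSE
  none <- select_parameter_set(s, tab)
  expect_false(none$found)
})

test_that("search reports can be serialized", {
  fd <- feature_design(wells = 4)
  fd$compounds <- fd$compounds[c("NicotineLike", "StimulantLike",
                                 "NegativeControl", "VehicleControl")]
  tab <- simulate_feature_table(fd, 909)
  des <- feature_design_roles(fd)
  s <- search_subsets(tab, des)
  f <- withr::local_tempfile(fileext = ".csv")
  write_search_report(s, f)
  rep <- utils::read.csv(f)
  expect_equal(nrow(rep), 8178L)
  expect_true(all(c("subset", "qualifies", "score") %in% names(rep)))
})
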