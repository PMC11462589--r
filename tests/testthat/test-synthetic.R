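test_that("well generation is reproducible and seed-sensitive", {
  p <- burst_process_params(recording_duration = 60, n_electrodes = 6)
  w1 <- generate_well(p, 123)
  w2 <- generate_well(p, 123)
  w3 <- generate_well(p, 124)
  expect_identical(lapply(w1$trains, as.numeric),
                   lapply(w2$trains, as.numeric))
  expect_false(identical(lapply(w1$trains, as.numeric),
                         lapply(w3$trains, as.numeric)))
  # caller RNG state untouched
  set.seed(1)
  before <- runif(1)
  set.seed(1)
  invisible(generate_well(p, 55))
  expect_identical(runif(1), before)
})

test_that("spike trains satisfy their invariants", {
  p <- burst_process_params()
  w <- generate_well(p, 9)
  for (tr in w$trains) {
    tt <- as.numeric(tr)
    if (length(tt) > 1) expect_true(all(diff(tt) > 0))
    if (length(tt)) {
      expect_gte(min(tt), 0)
      expect_lte(max(tt), p$recording_duration)
    }
  }
})

test_that("burst-sparse generation is recovered by detection", {
  p <- burst_process_params(background_rate = 0, nb_interval_mean = 90,
                            nb_duration_median = 0.5)
  counts <- vapply(1:6, function(s)
    nrow(detect_network_bursts(generate_well(p, 400 + s))), numeric(1))
  expect_true(all(abs(counts - 10) <= 1))
})

test_that("generator targets are recovered by the analyzer within 10%", {
  p <- burst_process_params()
  tgt <- expected_parameters(p)
  m <- rowMeans(vapply(1:8, function(s) {
    w <- make_well(1000 + s)
    compute_parameters(w, detect_network_bursts(w))[
      c("TS", "nNB", "IBI", "Duration", "Spikes", "MF")]
  }, numeric(6)))
  for (nm in names(tgt)) {
    expect_equal(unname(m[nm]), unname(tgt[nm]), tolerance = 0.1,
                 info = nm)
  }
})

test_that("compound profiles modulate parameters as dose-response curves", {
  base <- burst_process_params()
  d <- default_study_design()
  nic <- d$compounds$Nicotine

  expect_identical(apply_compound(base, nic, 0, "before_chronic"), base)
  # saturating dose approaches the maximum acute effect
  hi <- apply_compound(base, nic, 100, "before_chronic")
  occ100 <- 100^1.5 / (100^1.5 + 10^1.5)
  expect_equal(hi$background_rate,
               base$background_rate * (1 + 0.3 * occ100), tolerance = 1e-12)
  expect_error(apply_compound(base, nic, 2.5, "before_chronic"),
               "dose series")

  # non-addictive profiles never shift the burst-timing means
  for (nm in c("Varenicline", "Muscimol", "Amantadine", "Acetaminophen")) {
    prof <- d$compounds[[nm]]
    for (cc in prof$concentrations) {
      b <- apply_compound(base, prof, cc, "before_chronic")
      a <- apply_compound(base, prof, cc, "after_chronic")
      expect_equal(a$nb_interval_mean, b$nb_interval_mean, info = nm)
      expect_equal(a$nb_duration_median, b$nb_duration_median, info = nm)
    }
  }
  # addictive profiles do, and only after chronic exposure
  a <- apply_compound(base, nic, 100, "after_chronic")
  b <- apply_compound(base, nic, 100, "before_chronic")
  expect_gt(a$nb_interval_mean / b$nb_interval_mean, 1.5)

  expect_error(compound_profile("bad", "non_addictive", c(1, 10),
                                chronic = list(nb_interval_mean = 2)),
               "timing means")
})

test_that("the ethanol-like extinction clause empties top-dose wells", {
  d <- default_study_design()
  base <- d$base_params
  p <- apply_compound(base, d$compounds$Ethanol, 3, "after_chronic")
  expect_gt(p$nb_interval_mean, 100)
  w <- generate_well(p, 77)
  b <- detect_network_bursts(w)
  expect_lte(nrow(b), 2L)
  pv <- compute_parameters(w, b)
  expect_false(is.na(pv["TS"]))
})

test_that("study simulation is deterministic and well-structured", {
  d <- default_study_design()
  keep <- c("Nicotine", "DMSO")
  d$compounds <- d$compounds[keep]
  d$wells_per_compound <- d$wells_per_compound[keep]
  d$base_params <- burst_process_params(recording_duration = 120,
                                        n_electrodes = 6)
  f1 <- simulate_study_features(d, 321)
  f2 <- simulate_study_features(d, 321)
  expect_identical(f1, f2)
  expect_false(identical(f1, simulate_study_features(d, 322)))
  # one row per compound x well x phase x (baseline + doses)
  expect_equal(nrow(f1), 10 * 2 * 6 + 10 * 2 * 6)
  expect_setequal(unique(f1$phase), c("before_chronic", "after_chronic"))
  expect_true(all(table(f1$well, f1$phase) == 6))

  plates <- generate_study(d, 321)
  expect_s3_class(plates$before, "plate_recording")
  expect_equal(length(plates$before$wells), nrow(f1) / 2)
  # plate recordings carry the physical well in meta, dose step in the key
  k <- names(plates$before$wells)[1]
  expect_match(k, "@")
  expect_false(grepl("@", plates$before$wells[[k]]$meta$well_id))
})

test_that("feature-table generator plants shifts only where declared", {
  fd <- feature_design()
  tab <- simulate_feature_table(fd, 99)
  expect_identical(tab, simulate_feature_table(fd, 99))
  dose <- tab[tab$concentration > 0, ]
  shift <- function(cm, par) {
    a <- dose[dose$compound == cm & dose$phase == "after_chronic", par]
    b <- dose[dose$compound == cm & dose$phase == "before_chronic", par]
    mean(a) / mean(b)
  }
  # planted: NicotineLike moves IBI, not IMFI
  expect_gt(shift("NicotineLike", "IBI"), 1.2)
  expect_lt(abs(shift("NicotineLike", "IMFI") - 1), 0.1)
  # vehicle rows are unshifted noise around 100
  expect_equal(mean(dose$IBI[dose$compound == "VehicleControl"]), 100,
               tolerance = 5)
})

test_that("study designs survive a YAML round trip", {
  d <- default_study_design()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_study_design(d, f)
  back <- read_study_design(f)
  expect_equal(names(back$compounds), names(d$compounds))
  expect_equal(back$wells_per_compound, d$wells_per_compound)
  base <- back$base_params
  prof <- back$compounds$Nicotine
  expect_equal(apply_compound(base, prof, 10, "after_chronic"),
               apply_compound(d$base_params, d$compounds$Nicotine, 10,
                              "after_chronic"))
  w1 <- generate_well(apply_compound(base, prof, 10, "after_chronic"), 5)
  w2 <- generate_well(apply_compound(d$base_params, d$compounds$Nicotine,
                                     10, "after_chronic"), 5)
  expect_identical(lapply(w1$trains, as.numeric),
                   lapply(w2$trains, as.numeric))
})
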