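well_from_times <- function(times, electrodes = NULL, duration = 900,
                            n_electrodes = 8) {
  if (is.null(electrodes)) {
    electrodes <- rep_len(seq_len(n_electrodes), length(times))
  }
  trains <- lapply(seq_len(n_electrodes), function(e)
    spike_train(sprintf("E%d", e), sort(unique(times[electrodes == e])),
                duration))
  well_recording(recording_meta("w", "x", 0, "uM", "before_chronic",
                                duration), trains)
}

test_that("array-wide histogram pools electrodes and conserves spikes", {
  w <- well_from_times(seq(0, 0.099, length.out = 10))
  h <- array_wide_histogram(w)
  expect_equal(h[1], 10)
  expect_equal(sum(h), 10)
  expect_length(h, 9000)

  empty <- well_from_times(numeric(0))
  expect_equal(sum(array_wide_histogram(empty)), 0)
  expect_length(array_wide_histogram(empty), ceiling(900 / 0.1))

  set.seed(5)
  w2 <- well_from_times(runif(9000, 0, 900))
  expect_equal(sum(array_wide_histogram(w2)), 9000)
})

test_that("network-burst detection finds clusters and honours the merge gap", {
  expect_equal(nrow(detect_network_bursts(well_from_times(numeric(0)))), 0L)

  set.seed(7)
  cl <- function(at) at + sort(runif(200, 0, 0.5))
  w1 <- well_from_times(cl(100))
  b1 <- detect_network_bursts(w1)
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$n_spikes, 200L)

  w2 <- well_from_times(c(cl(100), cl(105)))
  expect_equal(nrow(detect_network_bursts(w2)), 2L)

  w3 <- well_from_times(c(cl(100), cl(100.75)))
  expect_equal(nrow(detect_network_bursts(w3)), 1L)
})

test_that("detection matches the brute-force reference on random wells", {
  for (seed in 1:25) {
    w <- random_small_well(seed)
    got <- detect_network_bursts(w)
    ref <- brute_force_bursts(w)
    expect_equal(nrow(got), nrow(ref), info = paste("seed", seed))
    if (nrow(ref)) {
      expect_equal(got$start_s, ref$start_s, info = paste("seed", seed))
      expect_equal(got$end_s, ref$end_s)
      expect_equal(got$n_spikes, ref$n_spikes)
      expect_equal(got$peak_bin_count, ref$peak_bin_count)
    }
  }
})

test_that("burst spike counts never exceed the well total and peaks are bounded", {
  for (seed in c(3, 9)) {
    w <- make_well(seed)
    b <- detect_network_bursts(w)
    ts <- sum(vapply(w$trains, length, integer(1)))
    expect_lte(sum(b$n_spikes), ts)
    expect_true(all(b$peak_bin_count <= b$n_spikes))
    expect_true(all(diff(b$start_s) > 0))
  }
})

test_that("burst count is robust to a half-bin shift of the histogram origin", {
  # periodic comb: shifting every spike by half a bin emulates an origin shift
  set.seed(13)
  base <- unlist(lapply(seq(5, 895, by = 10), function(at)
    at + sort(runif(80, 0, 0.4))))
  n0 <- nrow(detect_network_bursts(well_from_times(base)))
  n1 <- nrow(detect_network_bursts(well_from_times(base + 0.05)))
  expect_lte(abs(n1 - n0), 1L)
})

test_that("the 13 parameters follow their definitions", {
  # two clusters with known gap: NB1 ends near 100.5, NB2 starts near 102.5
  set.seed(17)
  t1 <- 100 + sort(runif(150, 0, 0.5))
  t2 <- 102.5 + sort(runif(150, 0, 0.5))
  w <- well_from_times(c(t1, t2))
  b <- detect_network_bursts(w)
  p <- compute_parameters(w, b)
  expect_equal(unname(p["nNB"]), 2)
  expect_equal(unname(p["IBI"]), min(t2) - max(t1), tolerance = 1e-12)
  expect_equal(unname(p["TS"]), 300)

  # MF averages the per-burst maximum bin count
  fake <- data.frame(start_s = c(1, 11, 21), end_s = c(2, 12, 22),
                     n_spikes = c(12, 12, 12), n_electrodes = 3,
                     peak_bin_count = c(3, 7, 2),
                     peak_time_s = c(1.5, 11.5, 21.5))
  p2 <- compute_parameters(w, fake)
  expect_equal(unname(p2["MF"]), mean(c(3, 7, 2)))

  # zero-dispersion durations
  fake$end_s <- fake$start_s + 1
  p3 <- compute_parameters(w, fake)
  expect_equal(unname(p3["CV_Duration"]), 0)
  expect_equal(unname(p3["Duration_IQR"]), 0)
})

test_that("wells with fewer than two bursts yield missing burst statistics", {
  w <- well_from_times(100 + sort(runif(150, 0, 0.5)))
  b <- detect_network_bursts(w)
  expect_equal(nrow(b), 1L)
  p <- compute_parameters(w, b)
  expect_equal(unname(p["nNB"]), 1)
  expect_false(is.na(p["TS"]))
  expect_false(is.na(p["Duration"]))
  expect_true(all(is.na(p[c("IBI", "IMFI", "CV_Duration", "Periodicity",
                            "Duration_IQR")])))

  silent <- well_from_times(numeric(0))
  p0 <- compute_parameters(silent, detect_network_bursts(silent))
  expect_equal(unname(p0["TS"]), 0)
  expect_equal(unname(p0["nNB"]), 0)
  expect_true(is.na(p0["Duration"]))
})

test_that("periodicity scores combs high, Poisson noise low, silence zero", {
  comb <- rep(0, 9000)
  comb[seq(1, 9000, by = 100)] <- 50    # burst every 10 s, 90 repeats
  expect_gte(periodicity(comb), 0.9)

  set.seed(23)
  pois <- rpois(9000, 2)
  expect_lt(periodicity(pois), 0.2)

  expect_equal(periodicity(rep(0, 9000)), 0)
  expect_equal(periodicity(rep(4, 9000)), 0)
})

test_that("vehicle normalization rescales per well and phase", {
  pars <- mea_parameters()
  mk_row <- function(well, conc, phase, ts) {
    v <- as.list(stats::setNames(rep(10, 13), pars))
    v$TS <- ts
    cbind(data.frame(well = well, compound = "x", concentration = conc,
                     unit = "uM", phase = phase, stringsAsFactors = FALSE),
          as.data.frame(v))
  }
  tab <- rbind(mk_row("W1", 0, "before_chronic", 50),
               mk_row("W1", 1, "before_chronic", 75))
  attr(tab, "normalized") <- FALSE
  class(tab) <- c("mea_features", "data.frame")
  norm <- normalize_to_vehicle(tab)
  expect_equal(norm$TS, c(100, 150))
  expect_equal(norm$IBI, c(100, 100))

  # zero baseline -> missing, with a message
  tab$Duration[1] <- 0
  expect_message(norm2 <- normalize_to_vehicle(tab), "zero baseline")
  expect_true(all(is.na(norm2$Duration)))
})

test_that("feature tables survive a tidy-CSV round trip", {
  fd <- feature_design(wells = 2)
  tab <- simulate_feature_table(fd, 31)
  f <- withr::local_tempfile(fileext = ".csv")
  write_features(tab, f)
  back <- read_features(f)
  back <- back[order(back$well, back$phase, back$concentration), ]
  tab2 <- tab[order(tab$well, tab$phase, tab$concentration), ]
  rownames(back) <- rownames(tab2) <- NULL
  expect_equal(back[, mea_parameters()], tab2[, mea_parameters()],
               tolerance = 1e-12)
  expect_true(attr(back, "normalized"))
})
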