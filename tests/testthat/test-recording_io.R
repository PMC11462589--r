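test_that("native spike-list reading handles plain, empty and unsorted files", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well,electrode,time_s", "W1,E1,0.1", "W1,E1,0.2",
               "W1,E1,0.3"), f)
  p <- read_spike_list(f)
  expect_length(p$wells, 1L)
  expect_equal(as.numeric(p$wells$W1$trains$E1), c(0.1, 0.2, 0.3))

  writeLines("well,electrode,time_s", f)
  expect_length(read_spike_list(f)$wells, 0L)

  writeLines(c("well,electrode,time_s", "W1,E1,0.3", "W1,E1,0.1",
               "W1,E1,0.2"), f)
  expect_equal(as.numeric(read_spike_list(f)$wells$W1$trains$E1),
               sort(c(0.3, 0.1, 0.2)))
})

test_that("malformed rows and unknown wells are reported", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well,electrode,time_s", "W1,E1,0.1", "W1,E1"), f)
  expect_error(read_spike_list(f), "line 3")
  writeLines(c("well,electrode,time_s", "W1,E1,zzz"), f)
  expect_error(read_spike_list(f), "line 2")

  writeLines(c("well,electrode,time_s", "W9,E1,0.1"), f)
  side <- paste0(tools::file_path_sans_ext(f), ".yaml")
  yaml::write_yaml(list(plate_id = "p", recording_duration = 10,
                        wells = list(W1 = list(compound = "x"))), side)
  on.exit(unlink(side), add = TRUE)
  expect_error(read_spike_list(f), "W9")
})

test_that("write/read round trip is lossless and byte-stable", {
  dir <- withr::local_tempdir()
  for (seed in 1:3) {
    params <- burst_process_params(recording_duration = 30, n_electrodes = 4)
    wells <- list(
      make_well(seed, params),
      well_recording(recording_meta("empty", "x", 1, "uM",
                                    "after_chronic", 30),
                     list(spike_train("E1", numeric(0), 30))))
    plate <- plate_recording("p", wells)
    f <- file.path(dir, sprintf("p%d.csv", seed))
    write_spike_list(plate, f)
    back <- read_spike_list(f)
    expect_equal(length(back$wells), length(plate$wells))
    for (k in names(plate$wells)) {
      w0 <- plate$wells[[k]]
      w1 <- back$wells[[k]]
      expect_equal(w1$meta$compound, w0$meta$compound)
      expect_equal(w1$meta$concentration, w0$meta$concentration)
      expect_equal(w1$meta$phase, w0$meta$phase)
      for (e in names(w0$trains)) {
        if (length(w0$trains[[e]])) {
          expect_identical(as.numeric(w1$trains[[e]]),
                           as.numeric(w0$trains[[e]]))
        }
      }
    }
  }
  # byte stability on a large plate
  big <- plate_recording("big", list(
    well_recording(recording_meta("W1", "x", 0, "uM", "before_chronic",
                                  1000),
                   list(spike_train("E1", sort(runif(1e5, 0, 1000)),
                                    1000)))))
  f1 <- file.path(dir, "b1.csv")
  f2 <- file.path(dir, "b2.csv")
  write_spike_list(big, f1)
  write_spike_list(big, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("vendor-style spike lists are read tolerantly", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("some preamble", "more preamble,,",
               "Time (s),Electrode,Amplitude (mV)",
               "0.10,A1_11,0.05", "0.20,A1_12,0.04", "0.30,B2_11,0.03"), f)
  p <- read_spike_list(f, dialect = "axion_compat")
  expect_setequal(names(p$wells), c("A1", "B2"))
  expect_equal(as.numeric(p$wells$A1$trains$`11`), 0.1)
  expect_equal(as.numeric(p$wells$B2$trains$`11`), 0.3)
})

test_that("high-pass filter rejects DC, keeps fast components, checks cutoff", {
  fs <- 12500
  t <- seq(0, 1, by = 1 / fs)
  dc <- raw_trace(rep(10, length(t)), fs)
  expect_lt(max(abs(highpass_filter(dc)$samples)), 1e-5)

  fast <- raw_trace(sin(2 * pi * 1000 * t), fs)
  out <- highpass_filter(fast)
  expect_equal(max(abs(out$samples[2000:10000])), 1, tolerance = 0.05)

  slow <- raw_trace(sin(2 * pi * 10 * t), fs)
  att <- max(abs(highpass_filter(slow)$samples[2000:10000]))
  expect_lt(20 * log10(att), -20)

  expect_error(highpass_filter(fast, cutoff_hz = 7000), "Nyquist")
})

test_that("noise sigma is robust to spikes and handles degenerate traces", {
  set.seed(11)
  fs <- 12500
  x <- rnorm(10 * fs, 0, 4)
  expect_equal(estimate_noise_sigma(raw_trace(x, fs)), 4, tolerance = 0.05)
  at <- sample(length(x) - 30, 50)
  for (a in at) x[a:(a + 20)] <- x[a:(a + 20)] + 40
  expect_equal(estimate_noise_sigma(raw_trace(x, fs)), 4, tolerance = 0.10)
  expect_warning(s0 <- estimate_noise_sigma(raw_trace(rep(0, fs), fs)))
  expect_equal(s0, 0)
})

test_that("threshold spike detection finds events of either polarity", {
  fs <- 12500
  x <- rep(0, fs)
  x[5000:5003] <- c(-10, -6, 4, 2)   # biphasic, extremum at sample 5000
  tr <- raw_trace(x, fs)
  expect_equal(detect_spikes(tr, sigma = 1), (5000 - 1) / fs)
  expect_length(detect_spikes(raw_trace(0.5 * x, fs), sigma = 1), 0L)
  # polarity flip invariance
  expect_equal(detect_spikes(raw_trace(-x, fs), sigma = 1),
               detect_spikes(tr, sigma = 1))
  expect_error(detect_spikes(raw_trace(rep(0, 2 * fs), fs), sigma = 0),
               "sigma")
})

test_that("events in noise are counted and false positives are calibrated", {
  set.seed(21)
  fs <- 12500
  x <- rnorm(20 * fs)
  at <- seq(0.5, 19.5, length.out = 100)
  for (a in at) {
    i <- round(a * fs)
    x[i] <- x[i] + 8
  }
  n <- length(detect_spikes(raw_trace(x, fs), k_sigma = 5.3, sigma = 1))
  expect_gte(n, 98)
  expect_lte(n, 102)
  # analytic two-sided exceedance calibration on white noise with known sigma
  set.seed(22)
  y <- rnorm(20 * fs)
  k <- 3.5
  expected <- 2 * pnorm(-k) * length(y)
  got <- length(detect_spikes(raw_trace(y, fs), k_sigma = k, sigma = 1))
  expect_lt(abs(got - expected), 4 * sqrt(expected))
  # at the 5.3-sigma working threshold noise alone yields essentially nothing
  expect_lte(length(detect_spikes(raw_trace(y, fs), k_sigma = 5.3,
                                  sigma = 1)), 1L)
})

test_that("raw-trace rendering of spikes feeds the detection path", {
  times <- seq(0.05, 1.95, by = 0.05)
  tr <- simulate_raw_trace(times, 2, amplitude = 60, noise_sd = 4, seed = 3)
  filt <- highpass_filter(tr)
  got <- detect_spikes(filt)
  expect_equal(length(got), length(times), tolerance = 0.05)
})
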