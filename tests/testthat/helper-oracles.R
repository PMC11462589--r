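# Independent reference implementations used as oracles. These deliberately
# avoid the package's vectorized code paths: plain loops over bins and spikes.

# brute-force four-step network-burst detection
brute_force_bursts <- function(well, cfg = burst_config()) {
  bw <- cfg$bin_ms / 1000
  dur <- well$meta$recording_duration
  tt <- sort(unlist(lapply(well$trains, as.numeric), use.names = FALSE))
  el <- character(0)
  for (tr in well$trains) {
    el <- c(el, rep(attr(tr, "electrode_id"), length(tr)))
  }
  el <- el[order(unlist(lapply(well$trains, as.numeric), use.names = FALSE))]
  nbin <- ceiling(dur / bw)
  counts <- integer(nbin)
  for (t in tt) {
    b <- min(nbin, floor(t / bw) + 1L)
    counts[b] <- counts[b] + 1L
  }
  thr <- cfg$rate_threshold
  if (is.null(thr)) {
    thr <- max(5, 0.25 * quantile(as.numeric(counts), 0.99, names = FALSE))
  }
  flagged <- counts >= thr
  gap_bins <- floor(cfg$merge_gap_ms / cfg$bin_ms)
  # state machine over bins: a run absorbs the next flagged bin when the
  # silent stretch since the last flagged bin is <= gap_bins
  runs <- list()
  cur <- NULL
  silent <- 0L
  for (b in seq_len(nbin)) {
    if (flagged[b]) {
      if (is.null(cur)) {
        cur <- c(b, b)
      } else if (silent <= gap_bins) {
        cur[2] <- b
      } else {
        runs[[length(runs) + 1L]] <- cur
        cur <- c(b, b)
      }
      silent <- 0L
    } else {
      silent <- silent + 1L
    }
  }
  if (!is.null(cur)) runs[[length(runs) + 1L]] <- cur
  active <- sum(vapply(well$trains, function(tr) length(tr) > 0L,
                       logical(1)))
  min_el <- max(1L, ceiling(cfg$min_electrode_frac * active))
  out <- NULL
  for (r in runs) {
    lo <- (r[1] - 1L) * bw
    hi <- r[2] * bw
    sel <- tt >= lo & tt < hi
    if (sum(sel) < cfg$min_spikes_per_nb) next
    if (length(unique(el[sel])) < min_el) next
    span <- r[1]:r[2]
    pk <- span[which.max(counts[span])]
    out <- rbind(out, data.frame(
      start_s = min(tt[sel]), end_s = max(tt[sel]), n_spikes = sum(sel),
      n_electrodes = length(unique(el[sel])),
      peak_bin_count = max(counts[span]),
      peak_time_s = (pk - 0.5) * bw))
  }
  if (is.null(out)) out <- data.frame(
    start_s = numeric(0), end_s = numeric(0), n_spikes = integer(0),
    n_electrodes = integer(0), peak_bin_count = integer(0),
    peak_time_s = numeric(0))
  out[order(out$start_s), , drop = FALSE]
}

# random small well for oracle-equivalence tests
random_small_well <- function(seed, duration = 60) {
  set.seed(seed)
  ne <- sample(4:8, 1)
  n_clusters <- sample(0:6, 1)
  centers <- runif(n_clusters, 1, duration - 1)
  tt <- c(runif(rpois(1, 2 * duration), 0, duration),
          unlist(lapply(centers, function(cc)
            cc + runif(rpois(1, 60), -0.25, 0.25))))
  tt <- tt[tt >= 0 & tt < duration]
  ee <- sample(ne, length(tt), replace = TRUE)
  trains <- lapply(seq_len(ne), function(e)
    spike_train(sprintf("E%d", e), sort(unique(tt[ee == e])), duration))
  well_recording(
    recording_meta("oracle", "none", 0, "uM", "before_chronic", duration),
    trains)
}

# quick default-profile well
make_well <- function(seed, params = burst_process_params(), compound = "x",
                      conc = 0, phase = "before_chronic") {
  generate_well(params, seed,
                recording_meta(paste0("w", seed), compound, conc, "uM",
                               phase, params$recording_duration))
}
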