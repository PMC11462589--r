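#' Network-burst detection configuration
#'
#' The four-step detector works on the array-wide spike-count histogram:
#' (1) pool all electrodes of a well into `bin_ms` bins; (2) flag bins whose
#' count reaches `rate_threshold` (fixed, default 10 spikes/bin; `NULL`
#' selects a per-well adaptive rule, `max(5, 0.25 * 99th-percentile bin
#' count)`, for preparations whose burst amplitude is unknown -- note the
#' adaptive rule ties the detected burst extent to the well's amplitude
#' distribution); (3) merge flagged runs
#' separated by at most `merge_gap_ms`; (4) keep candidates with at least
#' `min_spikes_per_nb` spikes that recruit at least `min_electrode_frac` of
#' the well's active electrodes. All four thresholds are configuration, not
#' constants: the method is a reconstruction and deployments tune it to their
#' preparation.
#'
#' @param bin_ms Histogram bin width in ms (default 100).
#' @param rate_threshold Spikes per bin needed to flag a bin (default 10), or
#'   `NULL` for the per-well adaptive rule.
#' @param merge_gap_ms Maximum silent gap merged into one burst (default 200).
#' @param min_spikes_per_nb Minimum spikes per network burst (default 10).
#' @param min_electrode_frac Minimum fraction of active electrodes that must
#'   fire inside the burst (default 0.25).
#' @return A `burst_config` list.
#' @export
burst_config <- function(bin_ms = 100, rate_threshold = 10,
                         merge_gap_ms = 200, min_spikes_per_nb = 10,
                         min_electrode_frac = 0.25) {
  stopifnot(bin_ms > 0, merge_gap_ms >= bin_ms, min_spikes_per_nb > 0,
            min_electrode_frac > 0, min_electrode_frac <= 1)
  if (!is.null(rate_threshold)) stopifnot(rate_threshold > 0)
  structure(list(bin_ms = bin_ms, rate_threshold = rate_threshold,
                 merge_gap_ms = merge_gap_ms,
                 min_spikes_per_nb = min_spikes_per_nb,
                 min_electrode_frac = min_electrode_frac),
            class = "burst_config")
}

#' Array-wide spike-count histogram
#'
#' Pools all electrodes of a well and counts spikes per `bin_ms` bin over the
#' whole recording (the AWSDR display quantity). The counts sum to the total
#' number of spikes in the well.
#'
#' @param well A [well_recording()].
#' @param bin_ms Bin width in ms.
#' @return Integer vector of per-bin counts; bin width and times are stored in
#'   attributes `bin_ms` and `t0`.
#' @export
array_wide_histogram <- function(well, bin_ms = 100) {
  stopifnot(inherits(well, "well_recording"), bin_ms > 0)
  dur <- well$meta$recording_duration
  nbin <- ceiling(dur / (bin_ms / 1000))
  tt <- pooled_spikes(well)
  counts <- integer(nbin)
  if (length(tt)) {
    b <- pmin(nbin, floor(tt / (bin_ms / 1000)) + 1L)
    tb <- tabulate(b, nbins = nbin)
    counts <- tb
  }
  structure(counts, bin_ms = bin_ms, t0 = 0)
}

#' Detect array-wide network bursts
#'
#' Runs the four-step method of [burst_config()] on a well. Burst bounds are
#' first snapped to bin edges, then refined to the first and last member
#' spike; the peak bin (largest count within the burst) provides the per-burst
#' maximum frequency and the burst's peak time (bin centre).
#'
#' @param well A [well_recording()].
#' @param cfg A [burst_config()].
#' @return A data frame of class `network_bursts` with columns `start_s`,
#'   `end_s`, `n_spikes`, `n_electrodes`, `peak_bin_count`, `peak_time_s`,
#'   sorted by start time. Zero rows when no burst qualifies.
#' @export
detect_network_bursts <- function(well, cfg = burst_config()) {
  stopifnot(inherits(well, "well_recording"), inherits(cfg, "burst_config"))
  counts <- array_wide_histogram(well, cfg$bin_ms)
  bw <- cfg$bin_ms / 1000
  thr <- cfg$rate_threshold
  if (is.null(thr)) {
    thr <- max(5, 0.25 * stats::quantile(as.numeric(counts), 0.99,
                                         names = FALSE, type = 7))
  }
  flagged <- which(counts >= thr)
  if (!length(flagged)) return(.empty_bursts())
  # runs of flagged bins merge when the silent stretch between them,
  # (diff - 1) bins, is at most merge_gap_ms
  gap_bins <- floor(cfg$merge_gap_ms / cfg$bin_ms)
  brk <- c(0L, which(diff(flagged) - 1L > gap_bins), length(flagged))
  # candidate bin ranges after merging runs separated by <= merge_gap
  tt <- pooled_spikes(well)
  el <- .spike_electrodes(well)
  n_active <- n_active_electrodes(well)
  min_el <- max(1L, ceiling(cfg$min_electrode_frac * n_active))
  n_cand <- length(brk) - 1L
  start_s <- end_s <- peak_time <- numeric(n_cand)
  n_spk <- n_el <- peak_cnt <- integer(n_cand)
  keep <- logical(n_cand)
  for (i in seq_len(n_cand)) {
    bins <- flagged[(brk[i] + 1L):brk[i + 1L]]
    lo <- (bins[1L] - 1L) * bw
    hi <- bins[length(bins)] * bw
    j1 <- findInterval(lo, tt, left.open = TRUE) + 1L
    j2 <- findInterval(hi, tt, left.open = TRUE)
    if (j2 - j1 + 1L < cfg$min_spikes_per_nb) next
    ue <- length(unique(el[j1:j2]))
    if (ue < min_el) next
    span <- bins[1L]:bins[length(bins)]
    pk <- span[which.max(counts[span])]
    keep[i] <- TRUE
    start_s[i] <- tt[j1]
    end_s[i] <- tt[j2]
    n_spk[i] <- j2 - j1 + 1L
    n_el[i] <- ue
    peak_cnt[i] <- counts[pk]
    peak_time[i] <- (pk - 0.5) * bw
  }
  if (!any(keep)) return(.empty_bursts())
  res <- data.frame(start_s = start_s[keep], end_s = end_s[keep],
                    n_spikes = n_spk[keep], n_electrodes = n_el[keep],
                    peak_bin_count = peak_cnt[keep],
                    peak_time_s = peak_time[keep])
  res <- res[order(res$start_s), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("network_bursts", "data.frame")
  res
}

.empty_bursts <- function() {
  res <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    n_spikes = integer(0), n_electrodes = integer(0),
                    peak_bin_count = integer(0), peak_time_s = numeric(0))
  class(res) <- c("network_bursts", "data.frame")
  res
}

# electrode label of each pooled spike, aligned with pooled_spikes()
.spike_electrodes <- function(well) {
  if (!length(well$trains)) return(character(0))
  tt <- unlist(lapply(well$trains, as.numeric), use.names = FALSE)
  el <- rep(names(well$trains), vapply(well$trains, length, integer(1)))
  el[order(tt)]
}
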