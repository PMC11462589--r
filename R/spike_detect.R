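#' Raw voltage trace
#'
#' @param samples Numeric vector of voltage samples (microvolts).
#' @param sampling_rate Sampling rate in Hz (default 12500, the acquisition
#'   rate assumed throughout).
#' @return A `raw_trace` object.
#' @export
raw_trace <- function(samples, sampling_rate = 12500) {
  stopifnot(is.numeric(samples), sampling_rate > 0)
  structure(list(samples = as.numeric(samples),
                 sampling_rate = as.numeric(sampling_rate)),
            class = "raw_trace")
}

#' Read a raw trace from flat binary
#'
#' Reads little-endian doubles (one channel) from `path`.
#'
#' @param path File of raw doubles.
#' @param sampling_rate Sampling rate in Hz.
#' @return A [raw_trace()].
#' @export
read_raw_trace <- function(path, sampling_rate = 12500) {
  n <- file.size(path) %/% 8L
  raw_trace(readBin(path, what = "double", n = n, size = 8L,
                    endian = "little"), sampling_rate)
}

#' Zero-phase high-pass filter
#'
#' 4th-order Butterworth high-pass applied forward-backward
#' ([signal::filtfilt()]), so the filter is zero-phase and spike times are not
#' shifted. The 200 Hz default removes field-potential and drift components
#' before threshold spike detection.
#'
#' @param trace A [raw_trace()].
#' @param cutoff_hz High-pass cutoff in Hz; must be below the Nyquist
#'   frequency.
#' @param order Butterworth order (default 4).
#' @return A filtered [raw_trace()] of the same length.
#' @export
highpass_filter <- function(trace, cutoff_hz = 200, order = 4) {
  stopifnot(inherits(trace, "raw_trace"))
  nyq <- trace$sampling_rate / 2
  if (cutoff_hz >= nyq) {
    stop("cutoff_hz (", cutoff_hz, ") must be below the Nyquist frequency (",
         nyq, ")")
  }
  bf <- signal::butter(order, cutoff_hz / nyq, type = "high")
  x <- trace$samples - mean(trace$samples)
  raw_trace(signal::filtfilt(bf, x), trace$sampling_rate)
}

#' Robust baseline-noise SD
#'
#' Estimates the SD of the baseline noise during quiescent periods: the trace
#' is cut into 1-s windows, the half with the lowest signal power is taken as
#' quiescent, and sigma is the median absolute deviation times 1.4826 over
#' those windows. This is insensitive to spikes, which are rare, large and
#' concentrated in high-power windows.
#'
#' @param trace A [raw_trace()], already high-pass filtered.
#' @return Estimated noise SD in the units of the trace.
#' @export
estimate_noise_sigma <- function(trace) {
  stopifnot(inherits(trace, "raw_trace"))
  x <- trace$samples
  fs <- trace$sampling_rate
  if (length(x) < fs) stop("need at least 1 s of samples")
  if (all(x == x[1L])) {
    warning("constant trace: sigma = 0")
    return(0)
  }
  nwin <- max(2L, floor(length(x) / fs))
  idx <- rep(seq_len(nwin), each = floor(length(x) / nwin))
  x <- x[seq_along(idx)]
  pow <- vapply(split(x, idx), function(w) mean(w^2), numeric(1))
  quiet <- names(sort(pow))[seq_len(ceiling(nwin / 2))]
  xs <- unlist(split(x, idx)[quiet], use.names = FALSE)
  stats::mad(xs, center = 0)
}

#' Threshold spike detection
#'
#' Detects spikes where the filtered signal exceeds `k_sigma` times the
#' baseline noise SD in either polarity. Samples above threshold are grouped
#' into events separated by at least the refractory window, and each event is
#' timed at its extreme-amplitude sample.
#'
#' @param trace A high-pass-filtered [raw_trace()].
#' @param k_sigma Threshold multiplier (default 5.3).
#' @param refractory_ms Minimum separation between events in ms (default 1).
#' @param sigma Noise SD; estimated with [estimate_noise_sigma()] when `NULL`.
#' @return Numeric vector of spike times in seconds.
#' @export
detect_spikes <- function(trace, k_sigma = 5.3, refractory_ms = 1,
                          sigma = NULL) {
  stopifnot(inherits(trace, "raw_trace"), k_sigma > 0)
  if (is.null(sigma)) sigma <- estimate_noise_sigma(trace)
  if (sigma <= 0) stop("sigma is 0: cannot form a detection threshold")
  x <- trace$samples
  fs <- trace$sampling_rate
  over <- which(abs(x) > k_sigma * sigma)
  if (!length(over)) return(numeric(0))
  gap <- max(1L, round(refractory_ms / 1000 * fs))
  brk <- c(0L, which(diff(over) > gap), length(over))
  times <- numeric(length(brk) - 1L)
  for (i in seq_len(length(brk) - 1L)) {
    ev <- over[(brk[i] + 1L):brk[i + 1L]]
    times[i] <- (ev[which.max(abs(x[ev]))] - 1L) / fs
  }
  times
}
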