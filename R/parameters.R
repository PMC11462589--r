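#' Names of the 13 analytical parameters
#'
#' `TS` (total spikes), `nNB` (number of network bursts), `IBI` (mean
#' end-to-next-start interval, s), `Duration` (mean NB duration, s), `Spikes`
#' (mean spikes per NB), `MF` (mean over NBs of the largest 100-ms bin count),
#' `IMFI` (mean peak-to-peak interval, s), the coefficients of variation of
#' Duration, Spikes, MF and IMFI, `Periodicity` (bounded autocorrelation
#' score), and `Duration_IQR` (interquartile range of NB durations, s).
#'
#' @return Character vector of length 13.
#' @export
mea_parameters <- function() {
  c("TS", "nNB", "IBI", "Duration", "Spikes", "MF", "IMFI",
    "CV_Duration", "CV_Spikes", "CV_MF", "CV_IMFI",
    "Periodicity", "Duration_IQR")
}

#' Periodicity of network activity
#'
#' Bounded periodicity score of the array-wide histogram: the normalized
#' autocorrelation of the mean-subtracted histogram is scanned for its largest
#' local maximum at lags of at least `min_lag` bins (up to half the recording)
#' and the height is clipped to `[0, 1]`. A perfectly periodic burst comb
#' scores near 1; a homogeneous Poisson histogram scores near 0; constant or
#' empty histograms score exactly 0.
#'
#' @param histogram Counts from [array_wide_histogram()] (any numeric vector).
#' @param min_lag Smallest lag considered, in bins (default 3).
#' @return Score in `[0, 1]`.
#' @export
periodicity <- function(histogram, min_lag = 3) {
  x <- as.numeric(histogram)
  n <- length(x)
  if (n < 2L * min_lag || stats::var(x) == 0) return(0)
  x <- x - mean(x)
  ac <- stats::acf(x, lag.max = floor(n / 2), plot = FALSE,
                   demean = FALSE)$acf[, 1L, 1L]
  # ac[1] is lag 0 (= 1); local maxima at lags >= min_lag
  r <- ac[-1L]
  k <- length(r)
  if (k < min_lag + 1L) return(0)
  is_max <- c(FALSE, r[2:(k - 1)] > r[1:(k - 2)] & r[2:(k - 1)] >= r[3:k],
              FALSE)
  cand <- which(is_max & seq_len(k) >= min_lag)
  if (!length(cand)) return(0)
  min(1, max(0, max(r[cand])))
}

#' Compute the 13 analytical parameters of one well
#'
#' Parameters that describe burst structure require at least two network
#' bursts; when `nNB < 2` they are reported as `NA` ("missing"), never as
#' zero, so that burst-free wells (e.g. activity extinguished at a top dose)
#' flow through the pipeline. `TS` and `nNB` are always defined; `Duration`,
#' `Spikes` and `MF` are defined from one burst onward. CVs use the sample SD
#' (n-1) and are `NA` with a warning when their mean is zero; `Duration_IQR`
#' uses linear-interpolation quartiles.
#'
#' @param well A [well_recording()].
#' @param bursts Result of [detect_network_bursts()] on the same well.
#' @param bin_ms Histogram bin width used for `Periodicity` (default 100).
#' @return Named numeric vector of length 13 (see [mea_parameters()]).
#' @export
compute_parameters <- function(well, bursts, bin_ms = 100) {
  stopifnot(inherits(well, "well_recording"), is.data.frame(bursts))
  p <- stats::setNames(rep(NA_real_, 13L), mea_parameters())
  p["TS"] <- length(pooled_spikes(well))
  n <- nrow(bursts)
  p["nNB"] <- n
  if (n >= 1L) {
    p["Duration"] <- mean(bursts$end_s - bursts$start_s)
    p["Spikes"] <- mean(bursts$n_spikes)
    p["MF"] <- mean(bursts$peak_bin_count)
  }
  if (n >= 2L) {
    ibi <- bursts$start_s[-1L] - bursts$end_s[-n]
    imfi <- diff(bursts$peak_time_s)
    p["IBI"] <- mean(ibi)
    p["IMFI"] <- mean(imfi)
    p["CV_Duration"] <- .cv(bursts$end_s - bursts$start_s)
    p["CV_Spikes"] <- .cv(bursts$n_spikes)
    p["CV_MF"] <- .cv(bursts$peak_bin_count)
    p["CV_IMFI"] <- .cv(imfi)
    p["Duration_IQR"] <- stats::IQR(bursts$end_s - bursts$start_s, type = 7)
    p["Periodicity"] <- periodicity(array_wide_histogram(well, bin_ms))
  }
  p
}

.cv <- function(x) {
  m <- mean(x)
  if (length(x) < 2L) return(NA_real_)
  if (m == 0) {
    warning("zero mean in a CV denominator; value set missing")
    return(NA_real_)
  }
  stats::sd(x) / m
}

#' Build a feature table from plate recordings
#'
#' Runs burst detection and parameter extraction on every well of one or more
#' plates and assembles the wide feature table used by the subset search: one
#' row per (well, compound, concentration, phase) with the 13 parameter
#' columns.
#'
#' @param plates A [plate_recording()] or list of them (e.g. the before- and
#'   after-chronic plates of a study).
#' @param cfg A [burst_config()].
#' @return A data frame of class `mea_features` with metadata columns `well`,
#'   `compound`, `concentration`, `unit`, `phase` followed by the 13
#'   parameters; attribute `normalized` is `FALSE`.
#' @export
extract_features <- function(plates, cfg = burst_config()) {
  if (inherits(plates, "plate_recording")) plates <- list(plates)
  rows <- lapply(plates, function(plate) {
    lapply(plate$wells, function(w) {
      p <- compute_parameters(w, detect_network_bursts(w, cfg), cfg$bin_ms)
      cbind(data.frame(well = w$meta$well_id, compound = w$meta$compound,
                       concentration = w$meta$concentration,
                       unit = w$meta$unit, phase = w$meta$phase,
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(p)))
    })
  })
  out <- do.call(rbind, unlist(rows, recursive = FALSE))
  rownames(out) <- NULL
  attr(out, "normalized") <- FALSE
  class(out) <- c("mea_features", "data.frame")
  out
}

#' Normalize features to the per-well vehicle baseline
#'
#' Every well has a solvent-only baseline recording (concentration 0) in each
#' phase; each dose value is expressed as percent of that baseline
#' (`100 * dose / vehicle`), per well, per parameter, per phase. Baseline rows
#' become exactly 100 for every defined parameter. A zero or missing baseline
#' value yields a missing normalized value (never infinity) and a message.
#'
#' @param features An unnormalized `mea_features` table from
#'   [extract_features()].
#' @return The normalized `mea_features` table (attribute `normalized` TRUE).
#' @export
normalize_to_vehicle <- function(features) {
  stopifnot(inherits(features, "mea_features"))
  if (isTRUE(attr(features, "normalized"))) return(features)
  pars <- mea_parameters()
  key <- interaction(features$well, features$phase, drop = TRUE)
  out <- features
  n_degenerate <- 0L
  for (g in levels(key)) {
    i <- which(key == g)
    base <- i[features$concentration[i] == 0]
    if (length(base) != 1L) {
      stop("well/phase group '", g, "' must have exactly one concentration-0 ",
           "baseline recording, found ", length(base))
    }
    b <- as.numeric(features[base, pars])
    bad <- is.na(b) | b == 0
    n_degenerate <- n_degenerate + sum(bad & !is.na(b))
    for (j in seq_along(pars)) {
      v <- features[i, pars[j]]
      out[i, pars[j]] <- if (bad[j]) NA_real_ else 100 * v / b[j]
    }
  }
  if (n_degenerate) {
    message("normalize_to_vehicle: ", n_degenerate,
            " zero baseline value(s); affected normalized values set missing")
  }
  attr(out, "normalized") <- TRUE
  out
}

#' Serialize a feature table to tidy CSV
#'
#' Long format `well,compound,concentration,unit,phase,parameter,value,
#' normalized`, deterministic row order.
#'
#' @param features An `mea_features` table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  pars <- mea_parameters()
  long <- do.call(rbind, lapply(pars, function(p)
    data.frame(features[, c("well", "compound", "concentration", "unit",
                            "phase")],
               parameter = p, value = features[[p]],
               normalized = isTRUE(attr(features, "normalized")))))
  long <- long[order(long$well, long$phase, long$concentration,
                     match(long$parameter, pars)), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read a tidy feature CSV written by [write_features()]
#'
#' @param path CSV path.
#' @return An `mea_features` table.
#' @export
read_features <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  wide <- stats::reshape(
    long[, c("well", "compound", "concentration", "unit", "phase",
             "parameter", "value")],
    idvar = c("well", "compound", "concentration", "unit", "phase"),
    timevar = "parameter", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide <- wide[, c("well", "compound", "concentration", "unit", "phase",
                   mea_parameters())]
  rownames(wide) <- NULL
  attr(wide, "normalized") <- isTRUE(long$normalized[1L])
  class(wide) <- c("mea_features", "data.frame")
  wide
}
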