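#' Spike train for one electrode
#'
#' A spike train is the ordered vector of spike times (seconds from recording
#' start) detected on one electrode. Times must be strictly increasing and lie
#' within `[0, recording_duration]`.
#'
#' @param electrode_id Electrode label (character scalar).
#' @param spike_times Numeric vector of spike times in seconds.
#' @param recording_duration Recording length in seconds used for validation.
#' @return A `spike_train` object (numeric vector with an `electrode_id`
#'   attribute).
#' @export
spike_train <- function(electrode_id, spike_times, recording_duration = 900) {
  stopifnot(is.character(electrode_id), length(electrode_id) == 1L)
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times, strictly = TRUE)) {
    spike_times <- sort(unique(spike_times))
  }
  if (length(spike_times) && (spike_times[1L] < 0 ||
      spike_times[length(spike_times)] > recording_duration)) {
    stop("spike times must lie in [0, recording_duration] for electrode ",
         electrode_id)
  }
  structure(spike_times, electrode_id = electrode_id, class = "spike_train")
}

#' Per-well recording metadata
#'
#' @param well_id Well label, unique within a plate.
#' @param compound Compound name; the vehicle control is identified by
#'   `compound == vehicle` in downstream steps.
#' @param concentration Numeric dose; 0 denotes the solvent-only baseline
#'   recording taken before cumulative dosing.
#' @param unit Concentration unit, typically `"uM"` or `"%"` (ethanol and DMSO
#'   doses are percentages).
#' @param phase `"before_chronic"` or `"after_chronic"`.
#' @param recording_duration Recording length in seconds (default 900, i.e.
#'   15 min of spontaneous activity per dose step).
#' @return A `recording_meta` list.
#' @export
recording_meta <- function(well_id, compound, concentration = 0, unit = "uM",
                           phase = c("before_chronic", "after_chronic"),
                           recording_duration = 900) {
  phase <- match.arg(phase)
  stopifnot(recording_duration > 0, is.numeric(concentration),
            concentration >= 0)
  structure(list(well_id = as.character(well_id),
                 compound = as.character(compound),
                 concentration = as.numeric(concentration),
                 unit = as.character(unit), phase = phase,
                 recording_duration = as.numeric(recording_duration)),
            class = "recording_meta")
}

#' One well of a multiwell MEA recording
#'
#' @param meta A [recording_meta()] object.
#' @param trains List of [spike_train()] objects; electrode ids must be unique
#'   within the well.
#' @return A `well_recording` object.
#' @export
well_recording <- function(meta, trains = list()) {
  stopifnot(inherits(meta, "recording_meta"))
  ids <- vapply(trains, function(tr) attr(tr, "electrode_id"), character(1))
  if (anyDuplicated(ids)) stop("duplicate electrode ids in well ", meta$well_id)
  names(trains) <- ids
  structure(list(meta = meta, trains = trains), class = "well_recording")
}

#' A plate of well recordings
#'
#' Groups all spike data of one recording session. "Plate" is used loosely: a
#' study phase may pool wells recorded across several physical plates.
#'
#' @param plate_id Plate label.
#' @param wells List of [well_recording()] objects with unique well ids.
#' @param keys Optional recording keys naming `wells`. Under cumulative
#'   dosing one physical well yields one recording per dose step; keys of the
#'   form `well@concentration` keep them distinct while `meta$well_id` stays
#'   the physical well.
#' @return A `plate_recording` object.
#' @export
plate_recording <- function(plate_id, wells = list(), keys = NULL) {
  ids <- vapply(wells, function(w) w$meta$well_id, character(1))
  if (is.null(keys)) keys <- ids
  stopifnot(length(keys) == length(wells))
  if (anyDuplicated(keys)) {
    stop("duplicate recording keys in plate ", plate_id)
  }
  names(wells) <- keys
  structure(list(plate_id = as.character(plate_id), wells = wells),
            class = "plate_recording")
}

#' @export
print.well_recording <- function(x, ...) {
  n <- sum(vapply(x$trains, length, integer(1)))
  cat(sprintf("<well_recording> %s  %s %g %s  %s\n  %d electrodes, %d spikes, %g s\n",
              x$meta$well_id, x$meta$compound, x$meta$concentration,
              x$meta$unit, x$meta$phase, length(x$trains), n,
              x$meta$recording_duration))
  invisible(x)
}

#' @export
print.plate_recording <- function(x, ...) {
  n <- sum(vapply(x$wells, function(w)
    sum(vapply(w$trains, length, integer(1))), numeric(1)))
  cat(sprintf("<plate_recording> %s: %d wells, %d spikes\n",
              x$plate_id, length(x$wells), n))
  invisible(x)
}

# all spike times of a well pooled across electrodes, sorted
pooled_spikes <- function(well) {
  if (!length(well$trains)) return(numeric(0))
  sort(unlist(lapply(well$trains, as.numeric), use.names = FALSE))
}

# number of electrodes with at least one spike
n_active_electrodes <- function(well) {
  sum(vapply(well$trains, function(tr) length(tr) > 0L, logical(1)))
}
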