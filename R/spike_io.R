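#' Read a multiwell spike list
#'
#' Native files are CSV with header `well,electrode,time_s` and an optional
#' YAML sidecar (same path with extension `.yaml`) carrying per-well metadata
#' (compound, concentration, unit, phase) plus `plate_id`,
#' `recording_duration` and the vehicle compound name. The `axion_compat`
#' dialect tolerantly reads vendor spike-list CSV exports: preamble lines are
#' skipped until a header mentioning both "Time" and "Electrode"; electrode
#' labels of the form `A1_12` are split into well `A1` and electrode `12`.
#'
#' Wells listed in the sidecar but absent from the CSV are created empty
#' (silent wells are legitimate). Spike rows for a well the sidecar does not
#' describe are a validation error.
#'
#' @param path CSV file path.
#' @param dialect `"native"` or `"axion_compat"`.
#' @param sidecar Optional sidecar path; defaults to `<path without ext>.yaml`
#'   when that file exists.
#' @return A [plate_recording()].
#' @export
read_spike_list <- function(path, dialect = c("native", "axion_compat"),
                            sidecar = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sidecar)) {
    cand <- paste0(tools::file_path_sans_ext(path), ".yaml")
    if (file.exists(cand)) sidecar <- cand
  }
  if (dialect == "native") {
    dat <- .read_native_rows(path)
  } else {
    dat <- .read_axion_rows(path)
  }
  meta <- if (!is.null(sidecar)) yaml::read_yaml(sidecar) else NULL
  plate_id <- if (!is.null(meta$plate_id)) meta$plate_id else
    tools::file_path_sans_ext(basename(path))
  duration <- if (!is.null(meta$recording_duration))
    as.numeric(meta$recording_duration)
  else if (nrow(dat)) max(dat$time_s) else 900
  side_wells <- names(meta$wells)
  csv_wells <- unique(dat$well)
  if (!is.null(side_wells)) {
    unknown <- setdiff(csv_wells, side_wells)
    if (length(unknown)) {
      stop("spike rows for well(s) not described in sidecar: ",
           paste(unknown, collapse = ", "))
    }
  }
  all_wells <- if (is.null(side_wells)) csv_wells else side_wells
  wells <- lapply(all_wells, function(w) {
    wm <- meta$wells[[w]]
    m <- recording_meta(
      well_id = if (!is.null(wm$well)) wm$well else w,
      compound = if (!is.null(wm$compound)) wm$compound else "",
      concentration = if (!is.null(wm$concentration))
        as.numeric(wm$concentration) else 0,
      unit = if (!is.null(wm$unit)) wm$unit else "uM",
      phase = if (!is.null(wm$phase)) wm$phase else "before_chronic",
      recording_duration = duration)
    rows <- dat[dat$well == w, , drop = FALSE]
    trains <- lapply(split(rows$time_s, rows$electrode), function(tt)
      sort(unique(as.numeric(tt))))
    trains <- trains[order(names(trains))]
    trains <- Map(function(id, tt) spike_train(id, tt, duration),
                  names(trains), trains)
    well_recording(m, unname(trains))
  })
  plate_recording(plate_id, wells, keys = all_wells)
}

.read_native_rows <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file (missing header): ", path)
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (!identical(trimws(tolower(header)), c("well", "electrode", "time_s"))) {
    stop("expected header 'well,electrode,time_s' in ", path)
  }
  body <- lines[-1L][nzchar(trimws(lines[-1L]))]
  if (!length(body)) {
    return(data.frame(well = character(0), electrode = character(0),
                      time_s = numeric(0)))
  }
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    stop("malformed spike-list row at line ", bad[1L] + 1L, " of ", path)
  }
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  tt <- suppressWarnings(as.numeric(m[, 3L]))
  if (anyNA(tt)) {
    stop("non-numeric spike time at line ", which(is.na(tt))[1L] + 1L,
         " of ", path)
  }
  data.frame(well = trimws(m[, 1L]), electrode = trimws(m[, 2L]), time_s = tt)
}

.read_axion_rows <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("Time", lines)
  hdr <- hdr[grepl("Electrode", lines[hdr])]
  if (!length(hdr)) {
    stop("no header line containing 'Time' and 'Electrode' in ", path)
  }
  hdr <- hdr[1L]
  cols <- trimws(strsplit(lines[hdr], ",", fixed = TRUE)[[1L]])
  i_time <- grep("Time", cols)[1L]
  i_el <- grep("Electrode", cols)[1L]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) {
    return(data.frame(well = character(0), electrode = character(0),
                      time_s = numeric(0)))
  }
  parts <- strsplit(body, ",", fixed = TRUE)
  keep <- lengths(parts) >= max(i_time, i_el)
  parts <- parts[keep]
  tt <- as.numeric(vapply(parts, `[[`, character(1), i_time))
  el <- trimws(vapply(parts, `[[`, character(1), i_el))
  well <- sub("_.*$", "", el)
  electrode <- ifelse(grepl("_", el), sub("^[^_]*_", "", el), el)
  data.frame(well = well, electrode = electrode, time_s = tt)
}

#' Write a multiwell spike list (native dialect)
#'
#' Writes the CSV (`well,electrode,time_s`, times at full double precision so
#' the round trip is lossless) and a YAML metadata sidecar at
#' `<path without ext>.yaml`. Output ordering is deterministic (wells,
#' electrodes and times sorted), so repeated writes are byte-identical.
#'
#' @param plate A [plate_recording()].
#' @param path Output CSV path.
#' @param vehicle Vehicle compound name stored in the sidecar (default
#'   `"DMSO"`).
#' @return `path`, invisibly.
#' @export
write_spike_list <- function(plate, path, vehicle = "DMSO") {
  stopifnot(inherits(plate, "plate_recording"))
  wells <- plate$wells[order(names(plate$wells))]
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines("well,electrode,time_s", con)
  for (k in names(wells)) {
    w <- wells[[k]]
    trains <- w$trains[order(names(w$trains))]
    for (tr in trains) {
      if (!length(tr)) next
      writeLines(sprintf("%s,%s,%.17g", k, attr(tr, "electrode_id"),
                         as.numeric(tr)), con)
    }
  }
  meta <- list(
    plate_id = plate$plate_id,
    recording_duration = if (length(wells))
      wells[[1L]]$meta$recording_duration else 900,
    vehicle = vehicle,
    wells = lapply(wells, function(w)
      list(well = w$meta$well_id,
           compound = w$meta$compound,
           concentration = w$meta$concentration,
           unit = w$meta$unit,
           phase = w$meta$phase)))
  yaml::write_yaml(meta, paste0(tools::file_path_sans_ext(path), ".yaml"))
  invisible(path)
}
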