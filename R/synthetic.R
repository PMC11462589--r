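#' Burst-process parameters of a simulated well
#'
#' The simulator emulates a mature cultured network on a multiwell MEA:
#' independent homogeneous Poisson background firing on each electrode, plus
#' array-wide network bursts from a Gamma renewal process. Each burst is an
#' inhomogeneous Poisson volley with trapezoidal intensity (sharp recruitment,
#' plateau, slower decay) over a LogNormal duration, shared across a random
#' subset of electrodes. Two multiplicative
#' noise sources act per 15-min recording: a "network state" fluctuation on
#' the rate parameters (firing levels drift considerably between recordings)
#' and a smaller one on the timing parameters (burst rhythm is more stable).
#'
#' @param background_rate Background firing rate, Hz per electrode.
#' @param nb_interval_mean Mean onset-to-onset network-burst interval, s.
#' @param nb_interval_shape Gamma shape of the renewal intervals.
#' @param nb_duration_median Median burst duration, s.
#' @param nb_duration_sdlog LogNormal sdlog of burst durations.
#' @param nb_peak_rate Expected array-wide spike count in the 100-ms bin at
#'   the burst intensity peak.
#' @param nb_amp_sdlog Per-burst amplitude dispersion (lognormal sdlog of a
#'   mean-one multiplier on burst intensity); drives the CVs of Spikes and MF.
#' @param nb_rise_frac,nb_fall_frac Fractions of the burst duration spent in
#'   the linear recruitment ramp and the decay ramp; the remainder is the
#'   plateau at peak intensity.
#' @param n_electrodes Electrodes per well.
#' @param participation Expected fraction of electrodes recruited per burst.
#' @param recording_duration Recording length, s.
#' @param rate_jitter_cv Per-recording CV of the rate parameters.
#' @param timing_jitter_cv Per-recording CV of the timing parameters.
#' @return A `burst_process_params` list.
#' @export
burst_process_params <- function(background_rate = 0.3,
                                 nb_interval_mean = 6,
                                 nb_interval_shape = 25,
                                 nb_duration_median = 0.4,
                                 nb_duration_sdlog = 0.35,
                                 nb_peak_rate = 40,
                                 nb_amp_sdlog = 0.3,
                                 nb_rise_frac = 0.15,
                                 nb_fall_frac = 0.3,
                                 n_electrodes = 16,
                                 participation = 0.75,
                                 recording_duration = 900,
                                 rate_jitter_cv = 0.15,
                                 timing_jitter_cv = 0.01) {
  p <- list(background_rate = background_rate,
            nb_interval_mean = nb_interval_mean,
            nb_interval_shape = nb_interval_shape,
            nb_duration_median = nb_duration_median,
            nb_duration_sdlog = nb_duration_sdlog,
            nb_peak_rate = nb_peak_rate, nb_amp_sdlog = nb_amp_sdlog,
            nb_rise_frac = nb_rise_frac, nb_fall_frac = nb_fall_frac,
            n_electrodes = as.integer(n_electrodes),
            participation = participation,
            recording_duration = recording_duration,
            rate_jitter_cv = rate_jitter_cv,
            timing_jitter_cv = timing_jitter_cv)
  stopifnot(background_rate >= 0, nb_interval_mean > 0,
            nb_interval_shape > 0, nb_duration_median > 0,
            nb_duration_sdlog >= 0, nb_peak_rate > 0, nb_amp_sdlog >= 0,
            nb_rise_frac > 0, nb_fall_frac > 0,
            nb_rise_frac + nb_fall_frac < 1, n_electrodes >= 1,
            participation > 0, participation <= 1, recording_duration > 0)
  structure(p, class = "burst_process_params")
}

# evaluate expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# deterministic substream seed from a study seed and integer indices
.substream <- function(seed, ...) {
  x <- as.double(seed) %% 2147483647
  for (i in c(...)) {
    x <- (x * 69069 + as.double(i) + 1) %% 2147483647
  }
  as.integer(max(1, x))
}

# lognormal multiplier with mean 1 and given CV
.ln_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdl^2 / 2, sdl))
}

# inverse-CDF sampler of the unit trapezoidal intensity profile on [0, 1]:
# linear rise over [0, r], plateau at 1, linear fall over [1 - f, 1]
.rtrap <- function(n, r, f) {
  A <- 1 - (r + f) / 2            # total area at unit height
  u <- stats::runif(n) * A
  a1 <- r / 2                     # area of the rise
  a2 <- a1 + (1 - r - f)          # area up to end of plateau
  out <- numeric(n)
  i1 <- u < a1
  out[i1] <- sqrt(2 * r * u[i1])
  i2 <- !i1 & u < a2
  out[i2] <- r + (u[i2] - a1)
  i3 <- !i1 & !i2
  out[i3] <- 1 - sqrt(pmax(0, 2 * f * (A - u[i3])))
  out
}

# CDF of the same trapezoid (for the measurement-model oracle)
.ptrap <- function(x, r, f) {
  A <- 1 - (r + f) / 2
  x <- pmin(pmax(x, 0), 1)
  ifelse(x < r, x^2 / (2 * r),
         ifelse(x <= 1 - f, r / 2 + (x - r),
                A - (1 - x)^2 / (2 * f))) / A
}

#' Simulate one well recording
#'
#' Fully reproducible from `seed`; the caller's RNG state is untouched.
#'
#' @param params A [burst_process_params()].
#' @param seed Integer seed of this well's substream.
#' @param meta Optional [recording_meta()]; a placeholder is built otherwise.
#' @return A [well_recording()].
#' @export
generate_well <- function(params, seed, meta = NULL) {
  stopifnot(inherits(params, "burst_process_params"))
  T <- params$recording_duration
  if (is.null(meta)) {
    meta <- recording_meta("sim", "none", 0, "uM", "before_chronic", T)
  }
  with_seed(seed, {
    r_mult <- .ln_mult(1, params$rate_jitter_cv)
    t_int <- .ln_mult(1, params$timing_jitter_cv)
    t_dur <- .ln_mult(1, params$timing_jitter_cv)
    m <- params$nb_interval_mean * t_int
    sh <- params$nb_interval_shape
    n_max <- ceiling(3 * T / m) + 10L
    gaps <- stats::rgamma(n_max, shape = sh, scale = m / sh)
    onsets <- stats::runif(1, 0, m) + c(0, cumsum(gaps))
    onsets <- onsets[onsets < T]
    n_nb <- length(onsets)
    durs <- stats::rlnorm(n_nb, log(params$nb_duration_median * t_dur),
                          params$nb_duration_sdlog)
    durs <- pmin(durs, pmax(0.01, T - onsets))
    ne <- params$n_electrodes
    el_ids <- sprintf("E%02d", seq_len(ne))
    spike_t <- vector("list", n_nb + 1L)
    spike_e <- vector("list", n_nb + 1L)
    lam_peak <- params$nb_peak_rate / 0.1 * r_mult
    area <- 1 - (params$nb_rise_frac + params$nb_fall_frac) / 2
    amps <- .ln_mult(n_nb, sqrt(exp(params$nb_amp_sdlog^2) - 1))
    for (i in seq_len(n_nb)) {
      n_sp <- stats::rpois(1, lam_peak * amps[i] * durs[i] * area)
      if (!n_sp) next
      tt <- onsets[i] + durs[i] * .rtrap(n_sp, params$nb_rise_frac,
                                         params$nb_fall_frac)
      tt <- tt[tt < T]
      n_sp <- length(tt)
      if (!n_sp) next
      k <- max(2L, min(ne, stats::rbinom(1, ne, params$participation)))
      members <- sample.int(ne, k)
      spike_t[[i]] <- tt
      spike_e[[i]] <- members[sample.int(k, n_sp, replace = TRUE)]
    }
    n_bg <- stats::rpois(ne, params$background_rate * r_mult * T)
    if (sum(n_bg)) {
      spike_t[[n_nb + 1L]] <- stats::runif(sum(n_bg), 0, T)
      spike_e[[n_nb + 1L]] <- rep(seq_len(ne), n_bg)
    }
    tt <- unlist(spike_t, use.names = FALSE)
    ee <- unlist(spike_e, use.names = FALSE)
    trains <- lapply(seq_len(ne), function(e) {
      spike_train(el_ids[e], tt[ee == e], T)
    })
    well_recording(meta, trains)
  })
}

#' Expected measured parameters of a burst process
#'
#' Predicts the headline analytical parameters that binned threshold
#' detection measures on wells generated from `params`, by an independent
#' Monte-Carlo measurement model: single bursts are drawn from the process
#' (LogNormal duration, triangular-intensity Poisson volley, per-recording
#' rate/timing jitter, Poisson background), binned on a randomly offset
#' 100-ms grid, thresholded and trimmed exactly as the four-step definition
#' prescribes -- but implemented separately from the analyzer, so the
#' generator-to-analyzer round trip is a genuine cross-check. `Duration`,
#' `Spikes` and `MF` therefore include bin-discretization and
#' threshold-truncation effects; `IBI` is the renewal mean minus the expected
#' measured duration.
#'
#' @param params A [burst_process_params()].
#' @param cfg The [burst_config()] the analysis will use.
#' @param reps Monte-Carlo replicates (default 2000).
#' @param seed Internal seed; the caller's RNG state is untouched.
#' @return Named vector: `TS`, `nNB`, `IBI`, `Duration`, `Spikes`, `MF`.
#' @export
expected_parameters <- function(params, cfg = burst_config(), reps = 2000,
                                seed = 20240101) {
  e_dur <- params$nb_duration_median * exp(params$nb_duration_sdlog^2 / 2)
  rate_nb <- 1 / params$nb_interval_mean
  trap_area <- 1 - (params$nb_rise_frac + params$nb_fall_frac) / 2
  total_spikes_per_nb <- params$nb_peak_rate / 0.1 * e_dur * trap_area
  bw <- cfg$bin_ms / 1000
  bg_tot <- params$background_rate * params$n_electrodes
  gap_bins <- floor(cfg$merge_gap_ms / cfg$bin_ms)
  meas <- with_seed(seed, {
    sims <- vector("list", reps)
    for (r in seq_len(reps)) {
      r_mult <- .ln_mult(1, params$rate_jitter_cv)
      t_dur <- .ln_mult(1, params$timing_jitter_cv)
      amp <- .ln_mult(1, sqrt(exp(params$nb_amp_sdlog^2) - 1))
      d <- stats::rlnorm(1, log(params$nb_duration_median * t_dur),
                         params$nb_duration_sdlog)
      lam <- params$nb_peak_rate / 0.1 * r_mult * amp
      n_sp <- stats::rpois(1, lam * d * trap_area)
      off <- stats::runif(1, 0, bw)
      tt <- off + d * .rtrap(n_sp, params$nb_rise_frac, params$nb_fall_frac)
      pad <- 3L
      lo <- -pad * bw
      n_bg <- stats::rpois(1, bg_tot * (d + off + 2 * pad * bw))
      tb <- stats::runif(n_bg, lo, d + off + pad * bw)
      allt <- c(tt, tb)
      edges <- seq(lo, d + off + pad * bw + bw, by = bw)
      cnt <- graphics::hist(allt, breaks = edges, plot = FALSE)$counts
      sims[[r]] <- list(allt = allt, edges = edges, cnt = cnt)
    }
    # adaptive threshold as the analysis applies it: max(5, 25% of the
    # well-histogram 99th percentile), reconstructed from burst bins plus
    # the background-only bins between bursts
    thr <- cfg$rate_threshold
    if (is.null(thr)) {
      burst_bins <- unlist(lapply(sims, `[[`, "cnt"), use.names = FALSE)
      n_quiet <- max(0L, round(reps * params$nb_interval_mean / bw) -
                       length(burst_bins))
      all_bins <- c(burst_bins, stats::rpois(n_quiet, bg_tot * bw))
      thr <- max(5, 0.25 * stats::quantile(as.numeric(all_bins), 0.99,
                                           names = FALSE, type = 7))
    }
    out <- matrix(NA_real_, reps, 3L,
                  dimnames = list(NULL, c("dur", "spikes", "mf")))
    for (r in seq_len(reps)) {
      allt <- sims[[r]]$allt
      edges <- sims[[r]]$edges
      cnt <- sims[[r]]$cnt
      flagged <- which(cnt >= thr)
      if (!length(flagged)) next
      brk <- c(0L, which(diff(flagged) - 1L > gap_bins), length(flagged))
      peak_bin <- which.max(cnt)
      run <- NULL
      for (b in seq_len(length(brk) - 1L)) {
        bins <- flagged[(brk[b] + 1L):brk[b + 1L]]
        if (peak_bin >= bins[1L] && peak_bin <= bins[length(bins)]) {
          run <- bins[1L]:bins[length(bins)]
          break
        }
      }
      if (is.null(run)) next
      wlo <- edges[run[1L]]
      whi <- edges[run[length(run)] + 1L]
      inside <- allt[allt >= wlo & allt < whi]
      if (length(inside) < cfg$min_spikes_per_nb) next
      out[r, ] <- c(max(inside) - min(inside), length(inside),
                    max(cnt[run]))
    }
    out
  })
  det <- mean(!is.na(meas[, 1L]))
  c(TS = params$recording_duration * rate_nb * total_spikes_per_nb +
      bg_tot * params$recording_duration,
    nNB = params$recording_duration * rate_nb * det,
    IBI = params$nb_interval_mean - mean(meas[, "dur"], na.rm = TRUE),
    Duration = mean(meas[, "dur"], na.rm = TRUE),
    Spikes = mean(meas[, "spikes"], na.rm = TRUE),
    MF = mean(meas[, "mf"], na.rm = TRUE))
}

#' Compound effect profile
#'
#' Acute dose-response effects are Hill-shaped multiplicative actions on the
#' burst-process parameters: at concentration `c` a parameter is multiplied
#' by `1 + (emax - 1) * occ(c)` with occupancy
#' `occ(c) = c^h / (c^h + ec50^h)` (so `occ(0) = 0`, and the multiplier tends
#' to `emax` at saturating dose). Effects may be facilitating (`emax > 1`) or
#' suppressing (`emax < 1`).
#'
#' Chronic shifts model a change in drug responsiveness after the chronic
#' exposure period: in the after-chronic phase each shifted parameter gains a
#' further multiplier `1 + (shift - 1) * occ_ref(c)` using the profile's
#' reference occupancy curve. The shift therefore vanishes at concentration 0
#' (the solvent-only baseline recording) and grows with dose, which is what
#' survives per-well, per-phase vehicle normalization and what produces a
#' concentration-dependent centroid shift. Non-addictive test profiles have
#' no chronic shift at all.
#'
#' @param name Compound name.
#' @param role `"addictive"`, `"non_addictive"` or `"vehicle"`.
#' @param concentrations Cumulative dose series (5-6 values).
#' @param unit Dose unit (`"uM"` or `"%"`).
#' @param acute Named list of acute effects, one entry per burst-process
#'   parameter: `c(emax, ec50, hill)`.
#' @param chronic Named list of chronic responsiveness shifts (parameter ->
#'   multiplier at full occupancy).
#' @param ref_ec50,ref_hill Reference occupancy curve for the chronic shift.
#' @param extinction_top_dose If TRUE, network bursting collapses at the top
#'   dose of the after-chronic session (burst interval inflated 200-fold),
#'   exercising the burst-free-well missing-value policy.
#' @return A `compound_profile` list.
#' @export
compound_profile <- function(name, role, concentrations, unit = "uM",
                             acute = list(), chronic = list(),
                             ref_ec50 = stats::median(concentrations),
                             ref_hill = 1.5,
                             extinction_top_dose = FALSE) {
  role <- match.arg(role, c("addictive", "non_addictive", "vehicle"))
  if (role == "non_addictive" &&
      any(c("nb_interval_mean", "nb_duration_median") %in% names(chronic))) {
    stop("non-addictive profiles must not shift burst-timing means ",
         "(nb_interval_mean, nb_duration_median); only addictive profiles ",
         "and the vehicle's solvent drift may")
  }
  structure(list(name = name, role = role,
                 concentrations = as.numeric(concentrations), unit = unit,
                 acute = acute, chronic = chronic, ref_ec50 = ref_ec50,
                 ref_hill = ref_hill,
                 extinction_top_dose = extinction_top_dose),
            class = "compound_profile")
}

.occ <- function(conc, ec50, hill) {
  if (conc <= 0) return(0)
  conc^hill / (conc^hill + ec50^hill)
}

#' Apply a compound profile to burst-process parameters
#'
#' @param base A [burst_process_params()].
#' @param profile A [compound_profile()].
#' @param concentration A dose from the profile's series, or 0 (baseline).
#' @param phase `"before_chronic"` or `"after_chronic"`.
#' @param sensitivity Per-well responsiveness multiplier (default 1): scales
#'   the magnitude of both acute and chronic effects, modelling well-to-well
#'   differences in drug sensitivity.
#' @return Modified [burst_process_params()].
#' @export
apply_compound <- function(base, profile, concentration,
                           phase = c("before_chronic", "after_chronic"),
                           sensitivity = 1) {
  phase <- match.arg(phase)
  stopifnot(inherits(base, "burst_process_params"),
            inherits(profile, "compound_profile"))
  if (concentration != 0 &&
      !any(abs(profile$concentrations - concentration) < 1e-12)) {
    stop("concentration ", concentration, " is not in the dose series of ",
         profile$name)
  }
  p <- base
  for (par in names(profile$acute)) {
    a <- profile$acute[[par]]
    p[[par]] <- p[[par]] * max(0.05, 1 + (a[[1L]] - 1) *
                                 .occ(concentration, a[[2L]], a[[3L]]) *
                                 sensitivity)
  }
  if (phase == "after_chronic") {
    occ <- .occ(concentration, profile$ref_ec50, profile$ref_hill)
    for (par in names(profile$chronic)) {
      p[[par]] <- p[[par]] * max(0.05, 1 + (profile$chronic[[par]] - 1) *
                                   occ * sensitivity)
    }
    if (profile$extinction_top_dose &&
        concentration == max(profile$concentrations)) {
      p$nb_interval_mean <- p$nb_interval_mean * 200
    }
  }
  p
}

#' Reference study designs
#'
#' `default_study_design()` mirrors the screening study: five addictive
#' profiles (nicotine, ethanol, flunitrazepam, phenobarbital,
#' methamphetamine), four non-addictive profiles (varenicline, muscimol,
#' amantadine, acetaminophen) and the DMSO vehicle, each with its cumulative
#' dose series, 10 wells per compound (8 for muscimol and amantadine), 15-min
#' recordings, 16 electrodes per well, and both phases. Addictive profiles
#' shift the burst-timing process (interval and duration, hence IBI,
#' Duration, IMFI and Duration IQR) after chronic exposure; non-addictive
#' profiles have identical responsiveness in both phases. The vehicle carries
#' a small dose-dependent solvent drift (escalating DMSO is not inert), which
#' gives the 2SD threshold a real, nonzero scale.
#'
#' `small_study_design()` is the scaled-down variant used for replicated
#' power/recovery simulations: 3 addictive + 2 non-addictive profiles plus
#' vehicle, 8 wells, 10-min recordings, 12 electrodes.
#'
#' @param wells_per_compound Optional named override of wells per compound.
#' @return A `study_design` list: `compounds` (list of
#'   [compound_profile()]), `wells_per_compound`, `base_params`,
#'   `baseline_rate_cv`, `baseline_timing_cv`.
#' @export
default_study_design <- function(wells_per_compound = NULL) {
  remodel <- list(nb_interval_shape = 0.35, nb_amp_sdlog = 1.35)
  profs <- list(
    compound_profile("Nicotine", "addictive", c(1, 3, 10, 30, 100), "uM",
      acute = list(background_rate = c(1.3, 10, 1.5),
                   nb_peak_rate = c(1.3, 10, 1.5),
                   nb_interval_mean = c(0.8, 10, 1.5)),
      chronic = c(list(nb_interval_mean = 2.2, nb_duration_median = 1.7,
                       nb_peak_rate = 0.8, background_rate = 1.5), remodel),
      ref_ec50 = 10),
    compound_profile("Ethanol", "addictive", c(0.03, 0.1, 0.3, 1, 3), "%",
      acute = list(nb_peak_rate = c(0.75, 0.5, 1.5),
                   nb_interval_mean = c(1.3, 0.5, 1.5)),
      chronic = c(list(nb_interval_mean = 2.0, nb_duration_median = 1.7,
                       nb_peak_rate = 0.8, background_rate = 0.65), remodel),
      ref_ec50 = 0.5, extinction_top_dose = TRUE),
    compound_profile("Flunitrazepam", "addictive", c(0.1, 0.3, 1, 3, 10),
      "uM",
      acute = list(nb_duration_median = c(1.25, 1, 1.5),
                   background_rate = c(0.9, 1, 1.5)),
      chronic = c(list(nb_interval_mean = 2.2, nb_duration_median = 1.6,
                       nb_peak_rate = 0.82, background_rate = 0.7), remodel),
      ref_ec50 = 1),
    compound_profile("Phenobarbital", "addictive", c(1, 3, 10, 30, 100),
      "uM",
      acute = list(nb_peak_rate = c(0.8, 10, 1.5),
                   nb_interval_mean = c(1.25, 10, 1.5)),
      chronic = c(list(nb_interval_mean = 2.0, nb_duration_median = 1.7,
                       nb_peak_rate = 0.8, background_rate = 0.65), remodel),
      ref_ec50 = 10),
    compound_profile("Methamphetamine", "addictive", c(0.3, 1, 3, 10, 30),
      "uM",
      acute = list(background_rate = c(1.4, 3, 1.5),
                   nb_interval_mean = c(0.85, 3, 1.5)),
      chronic = c(list(nb_interval_mean = 2.4, nb_duration_median = 1.6,
                       nb_peak_rate = 0.82, background_rate = 1.5), remodel),
      ref_ec50 = 3),
    compound_profile("Varenicline", "non_addictive", c(0.1, 0.3, 1, 3, 10),
      "uM",
      acute = list(background_rate = c(0.55, 1, 1.5),
                   nb_peak_rate = c(0.75, 1, 1.5),
                   nb_interval_mean = c(0.7, 1, 1.5),
                   nb_duration_median = c(0.8, 1, 1.5)),
      chronic = c(list(nb_peak_rate = 1.45, background_rate = 1.6), remodel),
      ref_ec50 = 1),
    compound_profile("Muscimol", "non_addictive",
      c(3, 10, 30, 100, 300, 1000), "uM",
      acute = list(background_rate = c(0.5, 30, 1.5),
                   nb_peak_rate = c(0.75, 30, 1.5),
                   nb_interval_mean = c(1.5, 30, 1.5),
                   nb_duration_median = c(1.25, 30, 1.5)),
      chronic = c(list(nb_peak_rate = 1.4, background_rate = 1.55), remodel),
      ref_ec50 = 30),
    compound_profile("Amantadine", "non_addictive", c(0.03, 0.1, 0.3, 1, 3),
      "uM",
      acute = list(background_rate = c(0.85, 0.3, 1.5),
                   nb_interval_mean = c(1.35, 0.3, 1.5),
                   nb_duration_median = c(1.25, 0.3, 1.5)),
      chronic = c(list(nb_peak_rate = 1.35, background_rate = 0.6), remodel),
      ref_ec50 = 0.3),
    compound_profile("Acetaminophen", "non_addictive", c(1, 3, 10, 30, 100),
      "uM",
      acute = list(background_rate = c(0.9, 10, 1.5),
                   nb_interval_mean = c(1.25, 10, 1.5),
                   nb_duration_median = c(1.2, 10, 1.5)),
      chronic = c(list(nb_peak_rate = 1.35, background_rate = 1.45), remodel),
      ref_ec50 = 10),
    compound_profile("DMSO", "vehicle", c(0.2, 0.3, 0.4, 0.5, 0.6), "%",
      acute = list(background_rate = c(0.92, 0.35, 2)),
      chronic = list(nb_interval_mean = 1.5, nb_duration_median = 1.35),
      ref_ec50 = 0.45, ref_hill = 4))
  names(profs) <- vapply(profs, `[[`, character(1), "name")
  wells <- stats::setNames(rep(10L, length(profs)), names(profs))
  wells[c("Muscimol", "Amantadine")] <- 8L
  if (!is.null(wells_per_compound)) {
    wells[names(wells_per_compound)] <- wells_per_compound
  }
  stopifnot(all(wells >= 8L))
  structure(list(compounds = profs, wells_per_compound = wells,
                 base_params = burst_process_params(),
                 baseline_rate_cv = 0.15, baseline_timing_cv = 0.08,
                 sensitivity_cv = 0.4),
            class = "study_design")
}

#' @rdname default_study_design
#' @export
small_study_design <- function() {
  d <- default_study_design()
  keep <- c("Nicotine", "Flunitrazepam", "Methamphetamine",
            "Varenicline", "Acetaminophen", "DMSO")
  d$compounds <- d$compounds[keep]
  d$wells_per_compound <- stats::setNames(rep(8L, length(keep)), keep)
  d$base_params <- burst_process_params(recording_duration = 600,
                                        n_electrodes = 12)
  d
}

#' Compound-role table of a study design
#'
#' @param design A `study_design`.
#' @return A [compound_design()] for the search and classifier.
#' @export
design_roles <- function(design) {
  compound_design(vapply(design$compounds, `[[`, character(1), "name"),
                  vapply(design$compounds, `[[`, character(1), "role"))
}

# iterate over every recording of a study; fn(meta, params, seed)
.study_apply <- function(design, seed, fn) {
  stopifnot(inherits(design, "study_design"))
  out <- list()
  for (ci in seq_along(design$compounds)) {
    prof <- design$compounds[[ci]]
    nw <- design$wells_per_compound[[prof$name]]
    for (wi in seq_len(nw)) {
      wid <- sprintf("%s_w%02d", toupper(substr(gsub("[^A-Za-z]", "",
                                                     prof$name), 1, 4)), wi)
      sens <- with_seed(.substream(seed, ci, wi, 99),
                        .ln_mult(1, design$sensitivity_cv))
      for (pi in 1:2) {
        phase <- c("before_chronic", "after_chronic")[pi]
        bl_seed <- .substream(seed, ci, wi, pi, 0)
        bl <- with_seed(bl_seed, list(
          rate = .ln_mult(1, design$baseline_rate_cv),
          timing = .ln_mult(1, design$baseline_timing_cv)))
        concs <- c(0, prof$concentrations)
        for (di in seq_along(concs)) {
          p <- design$base_params
          p$background_rate <- p$background_rate * bl$rate
          p$nb_peak_rate <- p$nb_peak_rate * bl$rate
          p$nb_interval_mean <- p$nb_interval_mean * bl$timing
          p$nb_duration_median <- p$nb_duration_median * bl$timing
          p <- apply_compound(p, prof, concs[di], phase, sensitivity = sens)
          meta <- recording_meta(wid, prof$name, concs[di], prof$unit,
                                 phase, p$recording_duration)
          out[[length(out) + 1L]] <-
            fn(meta, p, .substream(seed, ci, wi, pi, di))
        }
      }
    }
  }
  out
}

#' Simulate a full chronic-exposure study
#'
#' One recording per compound x well x phase x concentration (baseline 0 plus
#' the dose series), with per-well-and-phase biological baseline multipliers
#' shared across that well's dose steps. Returns the spike-level plates;
#' [simulate_study_features()] is the memory-light route straight to the
#' feature table.
#'
#' @param design A `study_design`.
#' @param seed Integer study seed; all randomness flows from it through
#'   documented per-recording substreams.
#' @return List with `before` and `after` [plate_recording()]s (recordings
#'   keyed by `well@concentration`).
#' @export
generate_study <- function(design, seed) {
  wells <- .study_apply(design, seed, function(meta, p, s) {
    generate_well(p, s, meta)
  })
  phase <- vapply(wells, function(w) w$meta$phase, character(1))
  keys <- vapply(wells, function(w)
    paste0(w$meta$well_id, "@", w$meta$concentration), character(1))
  mk <- function(ph, id) {
    sel <- phase == ph
    plate_recording(id, stats::setNames(wells[sel], keys[sel]),
                    keys = keys[sel])
  }
  list(before = mk("before_chronic", "before"),
       after = mk("after_chronic", "after"))
}

#' Simulate study features directly
#'
#' Generates each recording, runs burst detection and parameter extraction,
#' and discards the spikes, returning the raw (unnormalized) feature table of
#' the whole study.
#'
#' @param design A `study_design`.
#' @param seed Integer study seed (same substreams as [generate_study()]).
#' @param cfg A [burst_config()].
#' @return An `mea_features` table.
#' @export
simulate_study_features <- function(design, seed, cfg = burst_config()) {
  rows <- .study_apply(design, seed, function(meta, p, s) {
    w <- generate_well(p, s, meta)
    pv <- compute_parameters(w, detect_network_bursts(w, cfg), cfg$bin_ms)
    cbind(data.frame(well = meta$well_id, compound = meta$compound,
                     concentration = meta$concentration, unit = meta$unit,
                     phase = meta$phase, stringsAsFactors = FALSE),
          as.data.frame(as.list(pv)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "normalized") <- FALSE
  class(out) <- c("mea_features", "data.frame")
  out
}

#' Render spike times as a raw voltage trace
#'
#' Convolves spikes with a biphasic extracellular template and adds Gaussian
#' noise; used to exercise the threshold spike-detection path.
#'
#' @param spike_times Spike times, s.
#' @param duration Trace duration, s.
#' @param sampling_rate Hz (default 12500).
#' @param amplitude Peak template amplitude, uV.
#' @param noise_sd Gaussian noise SD, uV.
#' @param seed Substream seed for the noise.
#' @return A [raw_trace()].
#' @export
simulate_raw_trace <- function(spike_times, duration, sampling_rate = 12500,
                               amplitude = 40, noise_sd = 4, seed = 1) {
  n <- ceiling(duration * sampling_rate)
  i <- seq(0, 1.6e-3, by = 1 / sampling_rate)
  template <- -amplitude * exp(-((i - 4e-4) / 1.5e-4)^2) +
    0.45 * amplitude * exp(-((i - 9e-4) / 2.5e-4)^2)
  x <- with_seed(seed, stats::rnorm(n, 0, noise_sd))
  at <- round(spike_times * sampling_rate) + 1L
  for (a in at) {
    j <- a:min(n, a + length(template) - 1L)
    x[j] <- x[j] + template[seq_along(j)]
  }
  raw_trace(x, sampling_rate)
}

#' Export a study design as YAML
#'
#' Serializes the compound profiles, dose series, well counts and process
#' parameters of a [default_study_design()]-style design so a study layout
#' can be version-controlled and reloaded.
#'
#' @param design A `study_design`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_study_design <- function(design, path) {
  stopifnot(inherits(design, "study_design"))
  obj <- list(
    wells_per_compound = as.list(design$wells_per_compound),
    baseline_rate_cv = design$baseline_rate_cv,
    baseline_timing_cv = design$baseline_timing_cv,
    sensitivity_cv = design$sensitivity_cv,
    base_params = unclass(design$base_params),
    compounds = lapply(design$compounds, function(p)
      list(name = p$name, role = p$role,
           concentrations = p$concentrations, unit = p$unit,
           acute = lapply(p$acute, as.numeric),
           chronic = p$chronic, ref_ec50 = p$ref_ec50,
           ref_hill = p$ref_hill,
           extinction_top_dose = p$extinction_top_dose)))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a study design written by [write_study_design()]
#'
#' @param path YAML path.
#' @return A `study_design`.
#' @export
read_study_design <- function(path) {
  obj <- yaml::read_yaml(path)
  profs <- lapply(obj$compounds, function(p)
    compound_profile(p$name, p$role, unlist(p$concentrations), p$unit,
                     acute = p$acute, chronic = p$chronic,
                     ref_ec50 = p$ref_ec50, ref_hill = p$ref_hill,
                     extinction_top_dose = isTRUE(p$extinction_top_dose)))
  names(profs) <- vapply(profs, `[[`, character(1), "name")
  structure(list(
    compounds = profs,
    wells_per_compound = unlist(obj$wells_per_compound),
    base_params = do.call(burst_process_params,
                          obj$base_params[setdiff(names(obj$base_params),
                                                  character(0))]),
    baseline_rate_cv = obj$baseline_rate_cv,
    baseline_timing_cv = obj$baseline_timing_cv,
    sensitivity_cv = obj$sensitivity_cv), class = "study_design")
}
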