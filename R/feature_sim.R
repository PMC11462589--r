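#' Feature-level planted-effect table generator
#'
#' Generates a vehicle-normalized feature table (percent-of-baseline scale)
#' directly at the level of the 13 analytical parameters, for calibration and
#' recovery experiments on the subset search. Unlike the spike-level
#' simulator, this generator controls exactly which columns shift: at the
#' spike-process level the burst count and the mean burst interval are the
#' same quantity seen twice (`nNB ~ T / interval`), so no spike-level study
#' can shift IBI and IMFI while leaving nNB untouched -- the feature-level
#' generator can, which is what a planted-subset recovery experiment needs.
#'
#' Structure per row (compound x well x concentration x phase): multiplicative
#' LogNormal noise around 100 composed of a persistent per-well component
#' (the same culture is recorded in both phases, so part of each well's
#' deviation survives the chronic period; it cancels in before/after
#' contrasts while widening the within-group spread) plus per-recording
#' noise with family correlations (the interval readouts nNB/IBI/IMFI share
#' a latent factor, as do the duration readouts and the CVs). Addictive compounds shift the four burst-timing statistics (IBI,
#' Duration, IMFI, Duration_IQR) in the after-chronic phase, each compound
#' with its own emphasis so that every planted parameter is essential to
#' separating at least one compound. All test compounds (both classes) also
#' remodel the non-timing columns after chronic exposure (counts, rates and
#' CVs change dose-dependently), mirroring the observation that chronic
#' culture alters those dose-responses non-specifically. An optional
#' `after_noise_inflation` factor can make the after-chronic recordings
#' noisier than the before ones.
#'
#' @param design A [feature_design()].
#' @param seed Integer seed.
#' @return A normalized `mea_features` table.
#' @export
simulate_feature_table <- function(design = feature_design(), seed) {
  stopifnot(inherits(design, "feature_design"))
  pars <- mea_parameters()
  fam <- list(interval = c("nNB", "IBI", "IMFI"),
              duration = c("Duration", "Duration_IQR", "Spikes"),
              cv = c("CV_Duration", "CV_Spikes", "CV_MF", "CV_IMFI"))
  rows <- list()
  with_seed(seed, {
    for (cm in names(design$compounds)) {
      prof <- design$compounds[[cm]]
      for (w in seq_len(design$wells)) {
        wint <- stats::rnorm(13)        # persistent well identity, per column
        for (ph in c("before_chronic", "after_chronic")) {
          infl <- if (ph == "after_chronic") design$after_noise_inflation
          else 1
          for (cc in design$concentrations) {
            occ <- cc / (cc + design$ec50)
            f <- stats::setNames(stats::rnorm(length(fam)), names(fam))
            z <- stats::rnorm(13)
            names(z) <- pars
            for (fn in names(fam)) {
              rho <- design$family_rho
              z[fam[[fn]]] <- sqrt(rho) * f[[fn]] +
                sqrt(1 - rho) * z[fam[[fn]]]
            }
            sh <- design$well_effect_share
            zz <- sqrt(sh) * wint + sqrt(1 - sh) * z * infl
            val <- 100 * exp(zz * design$noise_sdlog)
            shifts <- c(prof$acute, if (ph == "after_chronic") prof$chronic)
            for (p in names(shifts)) {
              val[p] <- val[p] * (1 + (shifts[[p]] - 1) * occ)
            }
            rows[[length(rows) + 1L]] <- cbind(
              data.frame(well = sprintf("%s_w%02d", cm, w), compound = cm,
                         concentration = cc, unit = "uM", phase = ph,
                         stringsAsFactors = FALSE),
              as.data.frame(as.list(val)))
          }
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "normalized") <- TRUE
  class(out) <- c("mea_features", "data.frame")
  out
}

#' Design of a feature-level planted-effect study
#'
#' Five addictive profiles shift the burst-timing statistics after chronic
#' exposure, one timing statistic per compound (plus one compound shifting
#' all four moderately), so every member of the planted set
#' {IBI, Duration, IMFI, Duration_IQR} is necessary to separate at least one
#' addictive compound and the full set must be present to qualify; four
#' non-addictive profiles shift none of them. Every test compound remodels
#' the count/rate/CV columns after chronic exposure, so parameter sets
#' containing those columns are rejected by the addictive-only criterion.
#'
#' @param wells Wells per compound (default 8).
#' @param noise_sdlog Row noise sdlog (default 0.12, i.e. ~12% CV).
#' @param after_noise_inflation Noise multiplier in the after-chronic phase
#'   (default 1).
#' @param timing_shift Scale of the planted timing shifts (default 1;
#'   0 disables them for null studies).
#' @param well_effect_share Fraction of row variance carried by the
#'   persistent per-well component (default 0.7).
#' @return A `feature_design` list.
#' @export
feature_design <- function(wells = 8, noise_sdlog = 0.12,
                           after_noise_inflation = 1, timing_shift = 1,
                           well_effect_share = 0.7) {
  s <- function(x) 1 + (x - 1) * timing_shift
  # chronic remodeling of non-timing columns, common to both classes
  remodel <- function(k) {
    list(TS = 1 + 0.6 * k, nNB = 1 - 0.35 * k, Spikes = 1 + 0.55 * k,
         MF = 1 - 0.4 * k, CV_Spikes = 1 + 0.6 * k, CV_MF = 1 + 0.55 * k,
         CV_IMFI = 1 + 0.65 * k, CV_Duration = 1 + 0.5 * k,
         Periodicity = 1 - 0.45 * k)
  }
  cmp <- list(
    NicotineLike = c(remodel(1), list(IBI = s(1.8))),
    EthanolLike = c(remodel(-0.9), list(IMFI = s(1.8))),
    SedativeLike = c(remodel(-1), list(Duration = s(1.8))),
    BarbiturateLike = c(remodel(-0.8), list(Duration_IQR = s(1.8))),
    StimulantLike = c(remodel(0.9),
                      list(IBI = s(1.4), IMFI = s(1.4),
                           Duration = s(1.4), Duration_IQR = s(1.4))))
  non <- list(
    PartialAgonistLike = remodel(0.8),
    GabaergicLike = remodel(-1),
    DopaminergicLike = remodel(-0.7),
    NegativeControl = remodel(0.6))
  compounds <- c(
    lapply(cmp, function(ch) list(role = "addictive", acute = list(),
                                  chronic = ch)),
    lapply(non, function(ch) list(role = "non_addictive", acute = list(),
                                  chronic = ch)),
    list(VehicleControl = list(role = "vehicle", acute = list(),
                               chronic = list())))
  structure(list(compounds = compounds, wells = wells,
                 concentrations = c(1, 3, 10, 30, 100), ec50 = 10,
                 noise_sdlog = noise_sdlog,
                 after_noise_inflation = after_noise_inflation,
                 well_effect_share = well_effect_share,
                 family_rho = 0.45),
            class = "feature_design")
}

#' Compound-role table of a feature design
#'
#' @param design A `feature_design`.
#' @return A [compound_design()].
#' @export
feature_design_roles <- function(design) {
  compound_design(names(design$compounds),
                  vapply(design$compounds, `[[`, character(1), "role"))
}
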