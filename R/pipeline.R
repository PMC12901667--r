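#' Pipeline configuration for a full synthetic dispersal experiment
#'
#' Describes the experiment design - strains, replicate plates, and
#' fragmentation levels - together with the imaging schedule, inoculation
#' size, detection-noise model and tracking configuration, under a single
#' global seed from which each plate's random stream is derived
#' deterministically. The default design mirrors the study layout: 5
#' strains x 6 replicate plates (30 cultures), each plate holding a Short
#' and a Long landscape, imaged as 75-frame bursts every 12 min from t = 24
#' to t = 396 min, with ~1000 cells inoculated per landscape.
#'
#' @param strains named list of [strain_profile()] objects.
#' @param n_plates replicate plates per strain.
#' @param fragmentation fragmentation levels simulated per plate.
#' @param n_cells cells inoculated per landscape.
#' @param schedule a [burst_schedule()].
#' @param noise a [detection_noise()].
#' @param tracking a [tracking_config()].
#' @param seed global integer seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(strains = default_strain_profiles(),
                            n_plates = 6,
                            fragmentation = c("Short", "Long"),
                            n_cells = 1000,
                            schedule = burst_schedule(),
                            noise = detection_noise(),
                            tracking = tracking_config(),
                            seed = 1) {
  stopifnot(length(strains) >= 1, n_plates >= 1, n_cells >= 1,
            all(fragmentation %in% c("Short", "Long", "Control")),
            inherits(schedule, "burst_schedule"),
            inherits(noise, "detection_noise"),
            inherits(tracking, "tracking_config"))
  structure(list(strains = strains, n_plates = as.integer(n_plates),
                 fragmentation = fragmentation, n_cells = as.integer(n_cells),
                 schedule = schedule, noise = noise, tracking = tracking,
                 seed = seed),
            class = "pipeline_config")
}

#' Run the synthetic dispersal analysis pipeline end-to-end
#'
#' For every strain x plate x fragmentation landscape: simulate ground-truth
#' trajectories, derive noisy detections, link and filter trajectories,
#' compute per-trajectory traits, aggregate them per zone and time point,
#' and build dispersal and emigration curves with their termination and
#' half-dispersal summaries. Deterministic given the config (each landscape
#' consumes a seed derived from the global seed and its identifiers).
#'
#' @param config a [pipeline_config()].
#' @param verbose print per-landscape progress.
#' @return list with `traits` (per-trajectory records across landscapes),
#'   `zone_series` (zone x time aggregates), `curves` (per-landscape
#'   dispersal / emigration series) and `summaries` (per-landscape
#'   termination and time-until-half).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  traits_all <- list(); series_all <- list(); curves_all <- list()
  summ <- list()
  for (sname in names(config$strains)) {
    profile <- config$strains[[sname]]
    for (plate in seq_len(config$n_plates)) {
      for (frag in config$fragmentation) {
        id <- sprintf("%s.p%d.%s", sname, plate, frag)
        if (verbose) message("landscape ", id)
        spec <- build_default_landscape(frag)
        sd1 <- derive_seed(config$seed, sname, plate, frag, "truth")
        sd2 <- derive_seed(config$seed, sname, plate, frag, "detect")
        truth <- simulate_ground_truth(profile, spec, config$n_cells,
                                       schedule = config$schedule, seed = sd1)
        det <- detections_from_truth(truth, config$noise, seed = sd2,
                                     spec = spec)
        linked <- link_detections(det, config$tracking)
        kept <- filter_trajectories(linked, config$tracking)
        rec <- trajectory_traits(kept, spec)
        rec$strain <- sname; rec$plate <- plate; rec$fragmentation <- frag
        zser <- aggregate_zone_traits(rec)
        zser$strain <- sname; zser$plate <- plate; zser$fragmentation <- frag
        cv <- dispersal_curves(kept, spec, n_frames = config$schedule$frames,
                               id = id)
        term <- tryCatch(dispersal_at_termination(cv$curve),
                         error = function(e) NA_real_)
        t_half <- if (is.na(term)) NA_real_ else
          suppressWarnings(time_until_half(cv$curve, term))
        traits_all[[id]] <- rec
        series_all[[id]] <- zser
        curves_all[[id]] <- list(id = id, strain = sname, plate = plate,
                                 fragmentation = frag,
                                 dispersal = cv$curve,
                                 emigration = cv$emigration,
                                 abundances = cv$abundances)
        summ[[id]] <- data.frame(
          id = id, strain = sname, plate = plate, fragmentation = frag,
          dispersal_at_termination = term, time_until_half = t_half
        )
      }
    }
  }
  list(
    traits = do.call(rbind, traits_all),
    zone_series = do.call(rbind, series_all),
    curves = curves_all,
    summaries = {
      s <- do.call(rbind, summ); rownames(s) <- NULL; s
    }
  )
}

#' Plot a dispersal curve
#'
#' Rates over time, optionally with a LOESS smooth (presentation only; the
#' smooth never feeds any statistic).
#'
#' @param curve a [dispersal_curve()].
#' @param smooth add a LOESS smooth line.
#' @param span LOESS span.
#' @param ... passed to [plot()].
#' @return invisibly, the curve.
#' @export
plot_dispersal_curve <- function(curve, smooth = FALSE, span = 0.5, ...) {
  plot(curve$time_min, curve$rate, type = "b", pch = 16,
       xlab = "time (min)", ylab = "dispersal rate", ylim = c(0, 1), ...)
  if (smooth && sum(is.finite(curve$rate)) > 4) {
    fit <- stats::loess(rate ~ time_min, data = curve, span = span)
    tt <- seq(min(curve$time_min), max(curve$time_min), length.out = 200)
    graphics::lines(tt, stats::predict(fit, data.frame(time_min = tt)),
                    col = "red")
  }
  invisible(curve)
}
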