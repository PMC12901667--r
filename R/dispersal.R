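#' Per-zone abundance of a burst
#'
#' Cell abundance in a zone is the mean, over the frames of a burst, of the
#' number of trajectories detected on each frame in that zone (a trajectory
#' present on 37 of 75 frames contributes 37/75). Zones are assigned per
#' frame from the detection coordinates.
#'
#' @param trajectories linked detection table for one burst (columns
#'   `trajectory`, `frame`, `x_mm`, `y_mm`).
#' @param spec a [landscape_spec()].
#' @param n_frames number of frames in the burst (default 75).
#' @return named numeric vector of abundances per zone.
#' @export
abundance_per_zone <- function(trajectories, spec, n_frames = 75) {
  stopifnot(inherits(spec, "landscape_spec"), n_frames >= 1)
  zones <- if (spec$has_corridor) c("Start", "Corridor", "Target") else "Control"
  if (nrow(trajectories) == 0)
    return(stats::setNames(numeric(length(zones)), zones))
  z <- assign_zone(trajectories$x_mm, trajectories$y_mm, spec)
  counts <- table(factor(as.character(z), levels = zones))
  stats::setNames(as.numeric(counts) / n_frames, zones)
}

#' Dispersal rate from per-zone abundances
#'
#' Abundance in the Target patch divided by the total abundance across
#' Start, Corridor and Target.
#'
#' @param abundances named vector with entries `Start`, `Corridor`, `Target`.
#' @return a fraction in `[0, 1]`, `NA` (with a warning) if total is zero.
#' @export
#' @examples
#' dispersal_rate(c(Start = 50, Corridor = 25, Target = 25)) # 0.25
dispersal_rate <- function(abundances) {
  tot <- sum(abundances[c("Start", "Corridor", "Target")])
  if (!is.finite(tot) || tot <= 0) {
    warning("zero total abundance: dispersal rate undefined")
    return(NA_real_)
  }
  unname(abundances["Target"] / tot)
}

#' Emigration rate from per-zone abundances
#'
#' Summed abundance in the Corridor and Target divided by total abundance;
#' always at least the dispersal rate.
#'
#' @inheritParams dispersal_rate
#' @return a fraction in `[0, 1]`, `NA` (with a warning) if total is zero.
#' @export
emigration_rate <- function(abundances) {
  tot <- sum(abundances[c("Start", "Corridor", "Target")])
  if (!is.finite(tot) || tot <= 0) {
    warning("zero total abundance: emigration rate undefined")
    return(NA_real_)
  }
  unname((abundances["Corridor"] + abundances["Target"]) / tot)
}

#' Dispersal curve of one landscape
#'
#' @param time_min strictly increasing time points (min).
#' @param rate dispersal (or emigration) rates in `[0, 1]`.
#' @param id optional landscape identifier.
#' @return an object of class `dispersal_curve` (a data.frame).
#' @export
dispersal_curve <- function(time_min, rate, id = NULL) {
  stopifnot(length(time_min) == length(rate), all(diff(time_min) > 0),
            all(rate >= 0 & rate <= 1, na.rm = TRUE))
  structure(data.frame(time_min = time_min, rate = rate),
            id = id, class = c("dispersal_curve", "data.frame"))
}

#' Dispersal rate at termination
#'
#' The median of the five latest rates measured in a landscape.
#'
#' @param curve a [dispersal_curve()] (or data.frame with `time_min`,
#'   `rate`).
#' @return a fraction in `[0, 1]`.
#' @export
dispersal_at_termination <- function(curve) {
  r <- curve$rate[order(curve$time_min)]
  if (length(r) < 5) stop("need at least five time points")
  stats::median(utils::tail(r, 5))
}

#' Time until half dispersal
#'
#' The first time point at which half of the termination rate is strictly
#' exceeded.
#'
#' @param curve a [dispersal_curve()].
#' @param termination the termination rate; computed with
#'   [dispersal_at_termination()] if omitted.
#' @return time in min, or `NA` (with a warning) if half the termination
#'   value is never exceeded.
#' @export
time_until_half <- function(curve, termination = NULL) {
  if (is.null(termination)) termination <- dispersal_at_termination(curve)
  o <- order(curve$time_min)
  hit <- which(curve$rate[o] > termination / 2)
  if (length(hit) == 0) {
    warning("half of the termination rate is never exceeded")
    return(NA_real_)
  }
  curve$time_min[o][hit[1]]
}

#' Expansion front and rear of the Start-patch population
#'
#' The front is the 90% quantile and the rear the 10% quantile of the Y
#' coordinate of cells in the Start patch (the height above which only 10% /
#' 90% of cells are located), with linear-interpolation quantiles.
#'
#' @param y_mm Y coordinates (mm) of Start-patch cells.
#' @param min_n minimum sample size; below it both values are `NA`.
#' @return named vector `c(rear, front)` in mm.
#' @export
#' @examples
#' front_rear(1:10) # rear 1.9, front 9.1
front_rear <- function(y_mm, min_n = 10) {
  if (length(y_mm) < min_n)
    return(c(rear = NA_real_, front = NA_real_))
  q <- stats::quantile(y_mm, c(0.1, 0.9), names = FALSE, type = 7)
  c(rear = q[1], front = q[2])
}

#' Two-sample Kolmogorov-Smirnov comparison of zone distributions
#'
#' Compares the distribution of a movement trait between two zones at one
#' time point: the maximum absolute difference of the two empirical CDFs (D)
#' and its asymptotic p-value.
#'
#' @param values_a,values_b non-empty numeric samples.
#' @return list with `D` and `p_value`.
#' @export
ks_compare <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 1, length(values_b) >= 1)
  kt <- suppressWarnings(stats::ks.test(values_a, values_b, exact = FALSE))
  list(D = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Pairwise zone comparisons of a trait at each time point
#'
#' Applies [ks_compare()] to each zone pair (Start-Corridor, Start-Target,
#' Corridor-Target) at each time point. P-values are reported raw by
#' default, matching per-panel reporting of unadjusted pairwise tests; an
#' optional Holm adjustment (across all reported tests) is available.
#'
#' @param records per-trajectory records (output of [trajectory_traits()],
#'   or any data.frame with `zone`, `time_min` and the trait column).
#' @param trait trait column name (default `"speed_um_s"`).
#' @param min_n minimum per-zone sample size for a comparison.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return data.frame with `time_min`, `zone_a`, `zone_b`, `n_a`, `n_b`,
#'   `D`, `p_value`.
#' @export
compare_zone_distributions <- function(records, trait = "speed_um_s",
                                       min_n = 5,
                                       adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(trait %in% names(records))
  pairs <- list(c("Start", "Corridor"), c("Start", "Target"),
                c("Corridor", "Target"))
  rows <- list()
  for (t0 in sort(unique(records$time_min))) {
    rt <- records[records$time_min == t0, ]
    for (pr in pairs) {
      a <- rt[[trait]][rt$zone == pr[1]]
      b <- rt[[trait]][rt$zone == pr[2]]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) < min_n || length(b) < min_n) next
      k <- ks_compare(a, b)
      rows[[length(rows) + 1]] <- data.frame(
        time_min = t0, zone_a = pr[1], zone_b = pr[2],
        n_a = length(a), n_b = length(b), D = k$D, p_value = k$p_value
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time_min = numeric(), zone_a = character(),
               zone_b = character(), n_a = integer(), n_b = integer(),
               D = numeric(), p_value = numeric())
  if (adjust == "holm" && nrow(out) > 0)
    out$p_adjusted <- stats::p.adjust(out$p_value, "holm")
  out
}

#' Build dispersal and emigration curves from burst trajectories
#'
#' Computes per-zone abundances for every burst of a landscape and assembles
#' the dispersal-rate and emigration-rate time series.
#'
#' @param trajectories linked detection table spanning several bursts
#'   (columns `trajectory`, `time_min`, `frame`, `x_mm`, `y_mm`).
#' @param spec a [landscape_spec()].
#' @param n_frames frames per burst.
#' @param id optional landscape identifier.
#' @return list with `curve` (a [dispersal_curve()]), `emigration`
#'   (data.frame `time_min`, `rate`) and `abundances` (data.frame per burst
#'   x zone).
#' @export
dispersal_curves <- function(trajectories, spec, n_frames = 75, id = NULL) {
  times <- sort(unique(trajectories$time_min))
  ab <- lapply(times, function(t0) {
    abundance_per_zone(trajectories[trajectories$time_min == t0, , drop = FALSE],
                       spec, n_frames = n_frames)
  })
  disp <- vapply(ab, function(a) suppressWarnings(dispersal_rate(a)), 1)
  emig <- vapply(ab, function(a) suppressWarnings(emigration_rate(a)), 1)
  abdf <- do.call(rbind, lapply(seq_along(times), function(i) {
    data.frame(time_min = times[i], zone = names(ab[[i]]),
               abundance = as.numeric(ab[[i]]))
  }))
  list(
    curve = dispersal_curve(times, pmin(pmax(disp, 0), 1), id = id),
    emigration = data.frame(time_min = times, rate = emig),
    abundances = abdf
  )
}
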