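#' Swimming speed of a trajectory
#'
#' Gross displacement (summed step lengths) divided by the movement duration.
#'
#' @param x_mm,y_mm ordered trajectory coordinates (mm).
#' @param time_s ordered time stamps (s).
#' @return speed in um/s.
#' @export
#' @examples
#' swimming_speed(c(0, 0.155), c(0, 0), c(0, 1)) # 155 um/s
swimming_speed <- function(x_mm, y_mm, time_s) {
  stopifnot(length(x_mm) >= 2, length(x_mm) == length(y_mm),
            length(x_mm) == length(time_s))
  gross_mm <- sum(sqrt(diff(x_mm)^2 + diff(y_mm)^2))
  dur <- time_s[length(time_s)] - time_s[1]
  if (dur <= 0) stop("trajectory has zero duration")
  gross_mm * 1000 / dur
}

#' Trajectory linearity (straightness index)
#'
#' Net displacement (Euclidean distance between the start and end positions)
#' divided by the gross displacement (total path length); 1 is perfectly
#' straight, 0 a closed loop.
#'
#' @inheritParams swimming_speed
#' @return a fraction in `[0, 1]`, or `NA` (with a warning) if the gross
#'   displacement is zero.
#' @export
linearity <- function(x_mm, y_mm) {
  stopifnot(length(x_mm) >= 2, length(x_mm) == length(y_mm))
  gross <- sum(sqrt(diff(x_mm)^2 + diff(y_mm)^2))
  if (gross == 0) {
    warning("zero gross displacement: linearity undefined")
    return(NA_real_)
  }
  n <- length(x_mm)
  net <- sqrt((x_mm[n] - x_mm[1])^2 + (y_mm[n] - y_mm[1])^2)
  min(net / gross, 1)
}

#' Duration-corrected trajectory linearity
#'
#' Raw linearity is biased by trajectory duration: for tortuous motion the
#' net displacement grows like sqrt(t) while the gross displacement grows
#' like t, so short-lived trajectories look straighter. To compare
#' trajectories of unequal duration on an equal footing, linearity is
#' computed on non-overlapping sub-windows of a fixed reference duration and
#' averaged. Trajectories shorter than the reference window fall back to raw
#' linearity and are flagged.
#'
#' @inheritParams swimming_speed
#' @param reference_window_s sub-window duration (s), default 4.
#' @return list with `value` (corrected linearity) and `fallback` (logical,
#'   `TRUE` if the trajectory was shorter than the window).
#' @export
linearity_duration_corrected <- function(x_mm, y_mm, time_s,
                                         reference_window_s = 4) {
  stopifnot(length(x_mm) >= 2, reference_window_s > 0)
  dur <- time_s[length(time_s)] - time_s[1]
  if (dur < reference_window_s) {
    return(list(value = linearity(x_mm, y_mm), fallback = TRUE))
  }
  t0 <- time_s[1]
  win <- floor((time_s - t0) / reference_window_s)
  # drop the trailing partial window
  full <- win < floor(dur / reference_window_s)
  vals <- vapply(unique(win[full]), function(w) {
    ix <- which(win == w)
    # include the first point of the next window so windows abut
    nxt <- which(win == w + 1)
    if (length(nxt) > 0) ix <- c(ix, nxt[1])
    if (length(ix) < 2) return(NA_real_)
    linearity(x_mm[ix], y_mm[ix])
  }, 1)
  list(value = mean(vals, na.rm = TRUE), fallback = FALSE)
}

#' Per-trajectory trait records
#'
#' Computes the movement and morphology traits of every trajectory: swimming
#' speed, raw and duration-corrected linearity, cell size (trajectory-mean
#' area) and cell shape (trajectory-mean major axis over trajectory-mean
#' minor axis), plus the trajectory's zone and time point. A trajectory's
#' zone is the zone of the majority of its detections, with ties broken
#' toward the later zone along the dispersal axis.
#'
#' @param trajectories linked (and typically filtered) detection table with
#'   columns `trajectory`, `time_min`, `frame`, `time_s`, `x_mm`, `y_mm` and
#'   optionally `area_um2`, `major_um`, `minor_um`.
#' @param spec a [landscape_spec()].
#' @param reference_window_s window for the duration-bias correction (s).
#' @return data.frame with one row per trajectory: `trajectory`, `time_min`,
#'   `zone`, `n_detections`, `speed_um_s`, `linearity`,
#'   `linearity_corrected`, `linearity_fallback`, `size_um2`, `shape_ratio`.
#' @export
trajectory_traits <- function(trajectories, spec, reference_window_s = 4) {
  stopifnot(inherits(spec, "landscape_spec"))
  if (nrow(trajectories) == 0) {
    return(data.frame(trajectory = integer(), time_min = numeric(),
                      zone = factor(character(), levels = .zone_levels),
                      n_detections = integer(), speed_um_s = numeric(),
                      linearity = numeric(), linearity_corrected = numeric(),
                      linearity_fallback = logical(), size_um2 = numeric(),
                      shape_ratio = numeric()))
  }
  zone <- assign_zone(trajectories$x_mm, trajectories$y_mm, spec)
  # trajectories never span bursts: group by trajectory within burst
  key <- if ("time_min" %in% names(trajectories))
    interaction(trajectories$trajectory, trajectories$time_min, drop = TRUE)
  else trajectories$trajectory
  sp <- split(seq_len(nrow(trajectories)), key)
  rows <- lapply(sp, function(ix) {
    o <- ix[order(trajectories$frame[ix])]
    x <- trajectories$x_mm[o]; y <- trajectories$y_mm[o]
    tt <- trajectories$time_s[o]
    z <- zone[o]
    tab <- table(z)
    tab <- tab[tab > 0]
    # majority zone; ties toward the later zone along the dispersal axis
    winners <- names(tab)[tab == max(tab)]
    zlab <- winners[which.max(match(winners, .zone_levels))]
    lc <- linearity_duration_corrected(x, y, tt, reference_window_s)
    data.frame(
      trajectory = trajectories$trajectory[o[1]],
      time_min = if ("time_min" %in% names(trajectories))
        trajectories$time_min[o[1]] else NA_real_,
      zone = factor(zlab, levels = .zone_levels),
      n_detections = length(o),
      speed_um_s = swimming_speed(x, y, tt),
      linearity = suppressWarnings(linearity(x, y)),
      linearity_corrected = lc$value,
      linearity_fallback = lc$fallback,
      size_um2 = if ("area_um2" %in% names(trajectories))
        mean(trajectories$area_um2[o]) else NA_real_,
      shape_ratio = if ("major_um" %in% names(trajectories))
        mean(trajectories$major_um[o]) / mean(trajectories$minor_um[o])
      else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate trajectory traits per zone and time point
#'
#' Two-stage averaging: traits are first averaged over each trajectory (the
#' individual level, done in [trajectory_traits()]), then over all
#' trajectories identified in a given zone at each time point (the
#' population level), so every trajectory carries equal weight. Corridor and
#' Target time points with fewer than `min_trajectories` trajectories are
#' flagged as excluded.
#'
#' @param records output of [trajectory_traits()].
#' @param min_trajectories minimum trajectory count for Corridor / Target
#'   inclusion (default 5).
#' @return data.frame with one row per zone x time point: `zone`,
#'   `time_min`, `n_trajectories`, trait means, and `included`.
#' @export
aggregate_zone_traits <- function(records, min_trajectories = 5) {
  traits <- c("speed_um_s", "linearity", "linearity_corrected",
              "size_um2", "shape_ratio")
  if (nrow(records) == 0) {
    out <- data.frame(zone = factor(character(), levels = .zone_levels),
                      time_min = numeric(), n_trajectories = integer())
    for (tr in traits) out[[tr]] <- numeric()
    out$included <- logical()
    return(out)
  }
  key <- interaction(records$zone, records$time_min, drop = TRUE)
  sp <- split(seq_len(nrow(records)), key)
  rows <- lapply(sp, function(ix) {
    r1 <- records[ix[1], ]
    out <- data.frame(zone = r1$zone, time_min = r1$time_min,
                      n_trajectories = length(ix))
    for (tr in traits) out[[tr]] <- mean(records[[tr]][ix], na.rm = TRUE)
    out
  })
  out <- do.call(rbind, rows)
  out$included <- !(as.character(out$zone) %in% c("Corridor", "Target") &
                      out$n_trajectories < min_trajectories)
  out <- out[order(out$time_min, out$zone), ]
  rownames(out) <- NULL
  out
}

#' Window-average zone traits up to the time until half dispersal
#'
#' Restricts a zone time series to the early phase of dispersal - included
#' time points from the start of shooting to the population's time until
#' half dispersal - and averages each trait per zone over that window.
#'
#' @param series output of [aggregate_zone_traits()].
#' @param t_half time until half dispersal (min).
#' @param t_start first time point considered (min), default 24.
#' @return data.frame of per-zone means over the window.
#' @export
window_average <- function(series, t_half, t_start = 24) {
  stopifnot(t_half >= t_start)
  traits <- intersect(c("speed_um_s", "linearity", "linearity_corrected",
                        "size_um2", "shape_ratio"), names(series))
  sel <- series$included & series$time_min >= t_start &
    series$time_min <= t_half
  s <- series[sel, ]
  sp <- split(seq_len(nrow(s)), s$zone, drop = TRUE)
  rows <- lapply(names(sp), function(z) {
    ix <- sp[[z]]
    out <- data.frame(zone = factor(z, levels = .zone_levels),
                      n_time_points = length(ix))
    for (tr in traits) out[[tr]] <- mean(s[[tr]][ix], na.rm = TRUE)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Centre values by landscape within strain-by-fragmentation groups
#'
#' Visual centring used for cross-plate comparisons: for each value, the mean
#' of its plate (replicate landscape) within its strain x fragmentation group
#' is subtracted and the overall group mean added back, removing plate
#' offsets while preserving the group mean exactly.
#'
#' @param values numeric vector.
#' @param plate plate (replicate) identifier, parallel to `values`.
#' @param group strain x fragmentation group identifier, parallel to
#'   `values` (a single group if omitted).
#' @return centred numeric vector.
#' @export
center_by_landscape <- function(values, plate, group = NULL) {
  if (is.null(group)) group <- rep(1, length(values))
  stopifnot(length(values) == length(plate), length(values) == length(group))
  plate_in_group <- interaction(group, plate, drop = TRUE)
  values - stats::ave(values, plate_in_group) + stats::ave(values, group)
}
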