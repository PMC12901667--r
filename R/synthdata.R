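#' Strain movement / morphology profile for the synthetic generator
#'
#' Describes the trait distributions of one clonal strain used to generate
#' ground-truth trajectories. Speeds are drawn once per cell from a truncated
#' normal, sizes and axis ratios likewise; turning is a per-step normal
#' deviate on the heading. A movement strategy optionally modulates speed and
#' turning by the cell's current zone: a `"hump"` strain moves faster and
#' straighter in the corridor than in either patch, a `"slope"` strain slows
#' down monotonically across Start -> Corridor -> Target, and `"none"` applies
#' no zone modulation.
#'
#' @param name strain label.
#' @param speed_mean,speed_sd swimming speed distribution (um/s).
#' @param turning_sd SD of the per-step turning angle (radians) at the
#'   reference frame step (1/7.5 s).
#' @param size_mean,size_sd cell area distribution (um^2).
#' @param shape_mean,shape_sd major/minor axis-ratio distribution (>= 1).
#' @param strategy `"none"`, `"hump"` or `"slope"`.
#' @param zone_multipliers list with numeric vectors `speed` and `turning`,
#'   each named by zone, applied multiplicatively when `strategy != "none"`.
#'   Defaults encode the hump (corridor speed x1.3, straighter corridor) and
#'   slope (successive slow-down) patterns.
#' @param emigration_lag_min minutes during which cells are prevented from
#'   leaving the Start patch, emulating the initial reluctance to emigrate
#'   seen in real populations (0 = no lag).
#' @return an object of class `strain_profile`.
#' @export
strain_profile <- function(name,
                           speed_mean, speed_sd = 0.15 * speed_mean,
                           turning_sd = 0.35,
                           size_mean = 700, size_sd = 120,
                           shape_mean = 1.6, shape_sd = 0.2,
                           strategy = c("none", "hump", "slope"),
                           zone_multipliers = NULL,
                           emigration_lag_min = 0) {
  strategy <- match.arg(strategy)
  stopifnot(speed_mean > 0, speed_sd >= 0, turning_sd >= 0,
            size_mean > 0, shape_mean >= 1, emigration_lag_min >= 0)
  if (is.null(zone_multipliers)) {
    zone_multipliers <- switch(strategy,
      none = list(speed = c(Start = 1, Corridor = 1, Target = 1, Control = 1),
                  turning = c(Start = 1, Corridor = 1, Target = 1, Control = 1)),
      hump = list(speed = c(Start = 1, Corridor = 1.3, Target = 0.8, Control = 1),
                  turning = c(Start = 1, Corridor = 0.6, Target = 1.2, Control = 1)),
      slope = list(speed = c(Start = 1, Corridor = 0.85, Target = 0.7, Control = 1),
                   turning = c(Start = 1, Corridor = 1.2, Target = 1.4, Control = 1))
    )
  }
  stopifnot(all(zone_multipliers$speed > 0), all(zone_multipliers$turning > 0))
  structure(
    list(name = as.character(name),
         speed_mean = speed_mean, speed_sd = speed_sd,
         turning_sd = turning_sd,
         size_mean = size_mean, size_sd = size_sd,
         shape_mean = shape_mean, shape_sd = shape_sd,
         strategy = strategy, zone_multipliers = zone_multipliers,
         emigration_lag_min = emigration_lag_min),
    class = "strain_profile"
  )
}

#' Default panel of five synthetic strains
#'
#' Five clonal strains spanning slow to fast swimmers (means averaging about
#' 155 um/s across the panel) and the three observed movement strategies:
#' two "hump" strains (the faster pair, including one markedly fast strain),
#' two "slope" strains, and one strain with no zone pattern. Sizes and shapes
#' cover the typical Tetrahymena range (cell area a few hundred um^2, axis
#' ratio ~1.3-2).
#'
#' @return named list of [strain_profile()] objects.
#' @export
default_strain_profiles <- function() {
  list(
    D2 = strain_profile("D2", speed_mean = 120, strategy = "none",
                        shape_mean = 1.7, emigration_lag_min = 120),
    D4 = strain_profile("D4", speed_mean = 250, strategy = "hump",
                        turning_sd = 0.25, shape_mean = 1.8,
                        emigration_lag_min = 0),
    D11 = strain_profile("D11", speed_mean = 160, strategy = "hump",
                         emigration_lag_min = 90),
    D14 = strain_profile("D14", speed_mean = 140, strategy = "slope",
                         emigration_lag_min = 120),
    D21 = strain_profile("D21", speed_mean = 105, strategy = "slope",
                         size_mean = 800, emigration_lag_min = 150)
  )
}

#' Detection-noise model for synthetic particle tables
#'
#' @param detect_prob probability that a cell present on a frame yields a
#'   detection.
#' @param false_positive_rate expected number of spurious detections per
#'   frame (Poisson); spurious detections persist 1-2 frames, mimicking
#'   moving artifacts.
#' @param centroid_jitter_sd SD of the centroid localisation error (um).
#' @param area_jitter_cv coefficient of variation of the measured area.
#' @return an object of class `detection_noise`.
#' @export
detection_noise <- function(detect_prob = 1, false_positive_rate = 0,
                            centroid_jitter_sd = 0, area_jitter_cv = 0) {
  stopifnot(detect_prob >= 0, detect_prob <= 1, false_positive_rate >= 0,
            centroid_jitter_sd >= 0, area_jitter_cv >= 0)
  structure(list(detect_prob = detect_prob,
                 false_positive_rate = false_positive_rate,
                 centroid_jitter_sd = centroid_jitter_sd,
                 area_jitter_cv = area_jitter_cv),
            class = "detection_noise")
}

#' Simulate ground-truth cell trajectories in a landscape
#'
#' Generates a population of cells performing correlated random walks inside
#' the landscape, recorded only during the scheduled imaging bursts (the
#' snapshot design): positions are stored at frame resolution for each burst,
#' and cells advance with a coarser step between bursts. Per-cell speed,
#' size and shape are drawn once; a strategy profile modulates speed and
#' turning by the cell's current zone. With an emigration lag, cells cannot
#' cross from the Start patch into the corridor before the lag has elapsed.
#'
#' @param profile a [strain_profile()].
#' @param spec a [landscape_spec()].
#' @param n_cells number of cells to inoculate (>= 1).
#' @param schedule a [burst_schedule()].
#' @param seed integer seed (reproducible output).
#' @param dt_coarse time step (s) used between bursts.
#' @return list with `cells` (one row per cell: `cell_id`, `speed_um_s`,
#'   `size_um2`, `shape_ratio`) and `truth` (one row per cell x burst x
#'   frame: `cell_id`, `time_min`, `frame`, `time_s`, `x_mm`, `y_mm`).
#' @export
simulate_ground_truth <- function(profile, spec, n_cells,
                                  schedule = burst_schedule(), seed = 1,
                                  dt_coarse = 1) {
  stopifnot(inherits(profile, "strain_profile"),
            inherits(spec, "landscape_spec"),
            inherits(schedule, "burst_schedule"))
  if (n_cells < 1) stop("n_cells must be >= 1")
  with_seed(seed, {
    n <- as.integer(n_cells)
    speeds <- pmax(stats::rnorm(n, profile$speed_mean, profile$speed_sd), 1)
    sizes <- pmax(stats::rnorm(n, profile$size_mean, profile$size_sd),
                  0.05 * profile$size_mean)
    shapes <- pmax(stats::rnorm(n, profile$shape_mean, profile$shape_sd), 1)
    cells <- data.frame(cell_id = seq_len(n), speed_um_s = speeds,
                        size_um2 = sizes, shape_ratio = shapes)

    state <- sample_inoculum(n, spec)
    block_y <- if (profile$emigration_lag_min > 0 && spec$has_corridor)
      spec$patch_length else NULL
    lag_s <- profile$emigration_lag_min * 60
    zmult <- if (profile$strategy != "none") profile$zone_multipliers else NULL

    step_batch <- function(st, dt, n_steps, now_s) {
      blocking <- !is.null(block_y) && now_s < lag_s
      advance_agents(st, speeds,
                     profile$turning_sd * sqrt(dt / schedule$dt_fine),
                     dt, spec, block_y = if (blocking) block_y else NULL,
                     n_steps = n_steps, zone_multipliers = zmult)
    }
    advance_interval <- function(st, from_s, to_s) {
      # split at the lag boundary so blocking ends on time
      if (!is.null(block_y) && from_s < lag_s && to_s > lag_s) {
        st <- advance_interval(st, from_s, lag_s)
        return(advance_interval(st, lag_s, to_s))
      }
      remaining <- to_s - from_s
      n_full <- floor(remaining / dt_coarse)
      if (n_full > 0) st <- step_batch(st, dt_coarse, n_full, from_s)
      resid <- remaining - n_full * dt_coarse
      if (resid > 1e-9) st <- step_batch(st, resid, 1L, from_s)
      st
    }

    n_b <- length(schedule$times_min)
    nf <- schedule$frames
    out <- vector("list", n_b)
    now_s <- 0
    for (bi in seq_len(n_b)) {
      t_b <- schedule$times_min[bi]
      state <- advance_interval(state, now_s, t_b * 60)
      now_s <- t_b * 60
      xs <- matrix(0, nf, n); ys <- matrix(0, nf, n)
      xs[1, ] <- state$x; ys[1, ] <- state$y
      for (f in seq_len(nf - 1L) + 1L) {
        state <- step_batch(state, schedule$dt_fine, 1L, now_s)
        xs[f, ] <- state$x; ys[f, ] <- state$y
        now_s <- now_s + schedule$dt_fine
      }
      out[[bi]] <- data.frame(
        cell_id = rep(seq_len(n), each = nf),
        time_min = t_b,
        frame = rep(seq_len(nf), n),
        time_s = t_b * 60 + (rep(seq_len(nf), n) - 1) * schedule$dt_fine,
        x_mm = as.vector(xs), y_mm = as.vector(ys)
      )
    }
    list(cells = cells, truth = do.call(rbind, out))
  })
}

#' Derive a noisy detection table from ground truth
#'
#' Stands in for particle analysis on real frames: each true cell yields a
#' detection per frame with probability `detect_prob`, with jittered centroid
#' and jittered area/axes; spurious detections (false positives) appear at
#' uniform positions and persist 1-2 frames. The `source_id` column records
#' provenance (cell id, or `NA` for false positives) for validation only and
#' is never used by the tracker.
#'
#' @param truth output of [simulate_ground_truth()].
#' @param noise a [detection_noise()].
#' @param seed integer seed.
#' @param spec a [landscape_spec()] (needed to place false positives).
#' @return data.frame with columns `time_min`, `frame`, `time_s`, `x_mm`,
#'   `y_mm`, `area_um2`, `major_um`, `minor_um`, `source_id`.
#' @export
detections_from_truth <- function(truth, noise = detection_noise(), seed = 1,
                                  spec = NULL) {
  stopifnot(inherits(noise, "detection_noise"),
            all(c("cells", "truth") %in% names(truth)))
  tr <- truth$truth
  cells <- truth$cells
  with_seed(seed, {
    keep <- stats::runif(nrow(tr)) <= noise$detect_prob
    d <- tr[keep, , drop = FALSE]
    m <- nrow(d)
    jit <- noise$centroid_jitter_sd / 1000 # um -> mm
    area <- cells$size_um2[d$cell_id]
    ratio <- cells$shape_ratio[d$cell_id]
    if (noise$area_jitter_cv > 0) {
      area <- pmax(area * (1 + stats::rnorm(m, 0, noise$area_jitter_cv)),
                   0.05 * area)
    }
    # full axes of the ellipse with that area and axis ratio
    major <- 2 * sqrt(area * ratio / pi)
    minor <- 2 * sqrt(area / (ratio * pi))
    det <- data.frame(
      time_min = d$time_min, frame = d$frame, time_s = d$time_s,
      x_mm = d$x_mm + if (jit > 0) stats::rnorm(m, 0, jit) else 0,
      y_mm = d$y_mm + if (jit > 0) stats::rnorm(m, 0, jit) else 0,
      area_um2 = area, major_um = major, minor_um = minor,
      source_id = d$cell_id
    )
    if (noise$false_positive_rate > 0) {
      bursts <- unique(tr[, c("time_min", "frame", "time_s")])
      fp <- lapply(split(bursts, bursts$time_min), function(bf) {
        bf <- bf[order(bf$frame), ]
        # lifetimes are 1-2 frames (mean 1.5): spawn rate chosen so the
        # expected number of spurious detections PRESENT per frame matches
        # false_positive_rate
        nfp <- stats::rpois(1, noise$false_positive_rate * nrow(bf) / 1.5)
        if (nfp == 0) return(NULL)
        f0 <- sample(nrow(bf), nfp, replace = TRUE)
        life <- sample(1:2, nfp, replace = TRUE)
        pos <- sample_uniform_positions(nfp, spec)
        a0 <- stats::runif(nfp, 150, 1200)
        r0 <- stats::runif(nfp, 1, 2.5)
        rows <- lapply(seq_len(nfp), function(i) {
          fr <- f0[i]:min(f0[i] + life[i] - 1, nrow(bf))
          data.frame(
            time_min = bf$time_min[fr], frame = bf$frame[fr],
            time_s = bf$time_s[fr],
            x_mm = pos$x[i], y_mm = pos$y[i],
            area_um2 = a0[i],
            major_um = 2 * sqrt(a0[i] * r0[i] / pi),
            minor_um = 2 * sqrt(a0[i] / (r0[i] * pi)),
            source_id = NA_integer_
          )
        })
        do.call(rbind, rows)
      })
      fp <- do.call(rbind, fp)
      if (!is.null(fp)) det <- rbind(det, fp)
    }
    det <- det[order(det$time_min, det$frame, det$x_mm, det$y_mm), ]
    rownames(det) <- NULL
    det
  })
}

## Uniform positions over the accessible area (rejection sampling in the
## bounding box). Requires a landscape spec.
sample_uniform_positions <- function(n, spec) {
  if (is.null(spec))
    stop("a landscape_spec is required to place false positives")
  b <- zone_breaks(spec)
  ymax <- if (spec$has_corridor) b[["target_hi"]] else b[["start_hi"]]
  x <- numeric(n); y <- numeric(n); got <- 0L
  while (got < n) {
    m <- max(4L * (n - got), 16L)
    xx <- stats::runif(m, 0, spec$patch_width)
    yy <- stats::runif(m, 0, ymax)
    ok <- point_in_landscape(xx, yy, spec)
    k <- min(sum(ok), n - got)
    if (k > 0) {
      idx <- which(ok)[seq_len(k)]
      x[(got + 1):(got + k)] <- xx[idx]
      y[(got + 1):(got + k)] <- yy[idx]
      got <- got + k
    }
  }
  list(x = x, y = y)
}

#' Render a detection table as a grayscale frame stack
#'
#' Draws each detection as a bright ellipse (matching its area and axis
#' ratio) on a dark background, emulating darkfield imaging at 4 um/pixel.
#' Positions in mm map to continuous pixel coordinates as
#' `px = mm * 1000 / pixel_size_um`.
#'
#' @param detections detection table (needs `frame`, `x_mm`, `y_mm`,
#'   `major_um`, `minor_um`; optional `angle_rad` for the ellipse
#'   orientation, random if absent).
#' @param image_shape `c(nrow, ncol)` in pixels (rows index y, columns x).
#' @param pixel_size_um pixel edge length (um), default 4.
#' @param n_frames number of frames in the stack; defaults to
#'   `max(detections$frame)`.
#' @param background background intensity in `[0, 1)`.
#' @param intensity foreground intensity of rendered cells.
#' @param noise_sd SD of additive Gaussian pixel noise.
#' @param seed integer seed (orientation and noise).
#' @return list of `nrow x ncol` numeric matrices with values in `[0, 1]`.
#' @export
render_frames <- function(detections, image_shape, pixel_size_um = 4,
                          n_frames = NULL, background = 0.05,
                          intensity = 0.85, noise_sd = 0, seed = 1) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 1))
  nr <- as.integer(image_shape[1]); nc <- as.integer(image_shape[2])
  if (is.null(n_frames))
    n_frames <- if (nrow(detections) > 0) max(detections$frame) else 1L
  with_seed(seed, {
    ang <- if ("angle_rad" %in% names(detections)) detections$angle_rad
           else stats::runif(nrow(detections), 0, pi)
    frames <- lapply(seq_len(n_frames), function(f) {
      img <- matrix(background, nr, nc)
      rows <- which(detections$frame == f)
      for (i in rows) {
        cx <- detections$x_mm[i] * 1000 / pixel_size_um
        cy <- detections$y_mm[i] * 1000 / pixel_size_um
        a <- detections$major_um[i] / 2 / pixel_size_um # semi-axes, px
        b <- detections$minor_um[i] / 2 / pixel_size_um
        if (cx < 0 || cx > nc || cy < 0 || cy > nr)
          stop(sprintf("detection at (%.3f, %.3f) mm falls outside the image",
                       detections$x_mm[i], detections$y_mm[i]))
        th <- ang[i]
        jlo <- max(1L, floor(cx - a)); jhi <- min(nc, ceiling(cx + a) + 1L)
        ilo <- max(1L, floor(cy - a)); ihi <- min(nr, ceiling(cy + a) + 1L)
        if (jlo > jhi || ilo > ihi) next
        jj <- jlo:jhi; ii <- ilo:ihi
        # pixel (i, j) has centre (j - 0.5, i - 0.5) in continuous px coords
        px <- outer(rep(1, length(ii)), jj - 0.5) - cx
        py <- outer(ii - 0.5, rep(1, length(jj))) - cy
        u <- px * cos(th) + py * sin(th)
        v <- -px * sin(th) + py * cos(th)
        inside <- (u / a)^2 + (v / b)^2 <= 1
        sub <- img[ii, jj, drop = FALSE]
        sub[inside] <- intensity
        img[ii, jj] <- sub
      }
      if (noise_sd > 0) {
        img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
      }
      pmin(pmax(img, 0), 1)
    })
    frames
  })
}

#' Read or write a grayscale frame stack as multi-page TIFF
#'
#' @param frames list of numeric matrices in `[0, 1]`.
#' @param path file path.
#' @return `read_stack()` returns a list of matrices; `write_stack()` returns
#'   `path` invisibly.
#' @export
write_stack <- function(frames, path) {
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  x <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(x)) x <- list(x)
  x
}
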