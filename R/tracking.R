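#' Tracking configuration
#'
#' Parameters for particle detection, frame-to-frame linking, and trajectory
#' quality filtering. The gray threshold and size range select bright
#' particles of cell-like area; `max_step_um` is the distance gate for
#' linking (the maximum distance a cell can travel between frames, used to
#' discriminate cells from moving artifacts); the three quality thresholds
#' drop trajectories that are too short, too stationary, or too sparsely
#' detected. The default gate of 80 um/frame corresponds to ~600 um/s at
#' 7.5 fps, above the fastest strains.
#'
#' @param threshold gray threshold in `[0, 1]` separating bright particles
#'   from the dark background.
#' @param size_range_um2 `c(min, max)` particle area (um^2) accepted as a cell.
#' @param max_step_um linking distance gate (um per frame).
#' @param max_gap maximum number of missed frames a link may bridge.
#' @param min_duration_s minimum trajectory duration (s).
#' @param min_gross_um minimum gross displacement (um).
#' @param min_detect_freq minimum fraction of spanned frames on which the
#'   cell was detected, in `(0, 1]`.
#' @param pixel_size_um pixel edge length (um).
#' @param fps frames per second.
#' @return an object of class `tracking_config`.
#' @export
tracking_config <- function(threshold = 0.5, size_range_um2 = c(100, 2500),
                            max_step_um = 80, max_gap = 1,
                            min_duration_s = 2, min_gross_um = 20,
                            min_detect_freq = 0.5,
                            pixel_size_um = 4, fps = 7.5) {
  stopifnot(threshold > 0, length(size_range_um2) == 2,
            size_range_um2[1] > 0, size_range_um2[2] > size_range_um2[1],
            max_step_um > 0, max_gap >= 0, min_duration_s > 0,
            min_gross_um > 0, min_detect_freq > 0, min_detect_freq <= 1,
            pixel_size_um > 0, fps > 0)
  structure(list(threshold = threshold, size_range_um2 = size_range_um2,
                 max_step_um = max_step_um, max_gap = as.integer(max_gap),
                 min_duration_s = min_duration_s, min_gross_um = min_gross_um,
                 min_detect_freq = min_detect_freq,
                 pixel_size_um = pixel_size_um, fps = fps),
            class = "tracking_config")
}

#' Detect particles in a grayscale frame stack
#'
#' Per frame: threshold the image, label connected components (8-neighbour),
#' keep components whose area lies within the configured size range, and
#' summarise each as a detection with intensity-free moment features:
#' centroid, area, and major/minor axes of the second-moment-equivalent
#' ellipse. Pixel units are converted to um via `pixel_size_um`.
#'
#' @param frames list of numeric matrices (one per frame, values in `[0, 1]`;
#'   rows index y, columns x).
#' @param config a [tracking_config()].
#' @return detection data.frame with columns `frame`, `time_s`, `x_mm`,
#'   `y_mm`, `area_um2`, `major_um`, `minor_um`.
#' @export
detect_particles <- function(frames, config = tracking_config()) {
  stopifnot(inherits(config, "tracking_config"))
  if (length(frames) == 0) stop("empty frame stack")
  px <- config$pixel_size_um
  res <- lapply(seq_along(frames), function(f) {
    img <- frames[[f]]
    lab <- EBImage::bwlabel(img > config$threshold)
    nlab <- max(lab)
    if (nlab == 0) return(NULL)
    idx <- which(lab > 0)
    labs <- as.integer(lab[idx])
    nr <- nrow(img)
    row <- (idx - 1L) %% nr + 1L
    col <- (idx - 1L) %/% nr + 1L
    # continuous pixel coordinates of pixel centres
    xs <- col - 0.5
    ys <- row - 0.5
    npix <- tabulate(labs, nlab)
    sx <- rowsum(xs, labs)[, 1] / npix
    sy <- rowsum(ys, labs)[, 1] / npix
    # central second moments with the 1/12 within-pixel term
    vxx <- rowsum(xs^2, labs)[, 1] / npix - sx^2 + 1 / 12
    vyy <- rowsum(ys^2, labs)[, 1] / npix - sy^2 + 1 / 12
    vxy <- rowsum(xs * ys, labs)[, 1] / npix - sx * sy
    tr2 <- (vxx + vyy) / 2
    det2 <- sqrt(pmax(((vxx - vyy) / 2)^2 + vxy^2, 0))
    l1 <- pmax(tr2 + det2, 1e-12)
    l2 <- pmax(tr2 - det2, 1e-12)
    area <- npix * px^2
    keep <- area >= config$size_range_um2[1] & area <= config$size_range_um2[2]
    if (!any(keep)) return(NULL)
    data.frame(
      frame = f,
      time_s = (f - 1) / config$fps,
      x_mm = sx[keep] * px / 1000,
      y_mm = sy[keep] * px / 1000,
      area_um2 = area[keep],
      major_um = 4 * sqrt(l1[keep]) * px,
      minor_um = 4 * sqrt(l2[keep]) * px
    )
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(frame = integer(), time_s = numeric(),
                      x_mm = numeric(), y_mm = numeric(),
                      area_um2 = numeric(), major_um = numeric(),
                      minor_um = numeric())
  }
  rownames(out) <- NULL
  out
}

## Minimum-cost assignment (Jonker-Volgenant shortest augmenting paths).
## cost: n x m matrix, n <= m, finite entries. Returns integer vector of
## length n giving the column assigned to each row.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, all(is.finite(cost)))
  u <- numeric(n); v <- numeric(m)
  p <- integer(m + 1) # p[j + 1] = row matched to column j; j = 0 is virtual
  way <- integer(m)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      cur <- cost[i0, ] - u[i0] - v
      free <- !used[-1]
      upd <- free & cur < minv
      if (any(upd)) { minv[upd] <- cur[upd]; way[upd] <- j0 }
      jf <- which(free)
      j1 <- jf[which.min(minv[jf])]
      delta <- minv[j1]
      uu <- used[-1]
      u[p[c(TRUE, uu)]] <- u[p[c(TRUE, uu)]] + delta
      v[uu] <- v[uu] - delta
      minv[!uu] <- minv[!uu] - delta
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0L) assign[p[j + 1]] <- j
  assign
}

## Union-find for gate-component decomposition.
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Link detections across frames into trajectories
#'
#' Frame-to-frame assignment minimising total displacement among
#' track-detection pairs whose distance is within the gate
#' `max_step_um * (frames elapsed)`; among assignments of maximal
#' cardinality, the one with the smallest total distance is chosen (optimal
#' bipartite matching per frame pair, solved exactly). Tracks missing from up
#' to `max_gap` consecutive frames may be bridged; detections unmatched after
#' the gap window start new trajectories. Bursts (distinct `time_min`
#' values) are tracked independently and never bridged.
#'
#' @param detections detection data.frame (columns `frame`, `x_mm`, `y_mm`;
#'   optional `time_min` separating bursts).
#' @param config a [tracking_config()].
#' @return the detection table with an integer `trajectory` column, ordered
#'   by trajectory then frame.
#' @export
link_detections <- function(detections, config = tracking_config()) {
  stopifnot(inherits(config, "tracking_config"))
  if (nrow(detections) == 0) {
    detections$trajectory <- integer(0)
    return(detections)
  }
  if (!"time_min" %in% names(detections)) detections$time_min <- 0
  bursts <- split(seq_len(nrow(detections)), detections$time_min)
  traj <- integer(nrow(detections))
  next_id <- 1L
  gate0 <- config$max_step_um / 1000 # mm per frame
  BIG_UNMATCH <- 1e3
  BIG_FORBID <- 1e6
  for (b in bursts) {
    d <- detections[b, ]
    ord <- order(d$frame)
    d <- d[ord, ]
    bidx <- b[ord]
    # open track state
    t_x <- numeric(0); t_y <- numeric(0); t_frame <- integer(0)
    t_id <- integer(0)
    for (f in sort(unique(d$frame))) {
      di <- which(d$frame == f)
      nd <- length(di)
      act <- which(t_frame >= f - (config$max_gap + 1L) & t_frame < f)
      na <- length(act)
      matched_det <- rep(NA_integer_, nd) # track slot per detection
      if (na > 0 && nd > 0) {
        dx <- outer(t_x[act], d$x_mm[di], "-")
        dy <- outer(t_y[act], d$y_mm[di], "-")
        dist <- sqrt(dx^2 + dy^2)
        gate <- gate0 * (f - t_frame[act])
        ok <- dist <= gate # na x nd
        if (any(ok)) {
          # connected components over the gated bipartite graph
          parent <- seq_len(na + nd)
          ed <- which(ok, arr.ind = TRUE)
          for (e in seq_len(nrow(ed))) {
            a <- uf_find(parent, ed[e, 1])
            z <- uf_find(parent, na + ed[e, 2])
            if (a != z) parent[a] <- z
          }
          roots <- vapply(seq_len(na + nd), function(i) uf_find(parent, i), 1L)
          for (comp in unique(roots)) {
            rows <- which(roots[seq_len(na)] == comp)
            cols <- which(roots[na + seq_len(nd)] == comp)
            if (length(rows) == 0 || length(cols) == 0) next
            if (length(rows) == 1 && length(cols) == 1) {
              if (ok[rows, cols]) matched_det[cols] <- act[rows]
              next
            }
            cc <- dist[rows, cols, drop = FALSE]
            cc[!ok[rows, cols, drop = FALSE]] <- BIG_FORBID
            # dummy columns allow tracks to stay unmatched
            cc <- cbind(cc, matrix(BIG_UNMATCH, length(rows), length(rows)))
            sol <- solve_assignment(cc)
            real <- sol <= length(cols)
            matched_det[cols[sol[real]]] <- act[rows[real]]
          }
        }
      }
      # update matched tracks, open new ones for unmatched detections
      for (k in seq_len(nd)) {
        if (!is.na(matched_det[k])) {
          s <- matched_det[k]
          t_x[s] <- d$x_mm[di[k]]; t_y[s] <- d$y_mm[di[k]]
          t_frame[s] <- f
          traj[bidx[di[k]]] <- t_id[s]
        } else {
          t_x <- c(t_x, d$x_mm[di[k]]); t_y <- c(t_y, d$y_mm[di[k]])
          t_frame <- c(t_frame, f)
          t_id <- c(t_id, next_id)
          traj[bidx[di[k]]] <- next_id
          next_id <- next_id + 1L
        }
      }
    }
  }
  detections$trajectory <- traj
  detections[order(detections$trajectory, detections$frame), ]
}

#' Filter trajectories by quality criteria
#'
#' Keeps trajectories whose duration, gross displacement and detection
#' frequency (detections over frames spanned) pass the configured minima,
#' removing stationary artifacts, fleeting false positives and sparsely
#' detected cells.
#'
#' @param trajectories linked detection table (output of
#'   [link_detections()]; needs `trajectory`, `frame`, `time_s`, `x_mm`,
#'   `y_mm`).
#' @param config a [tracking_config()].
#' @return the surviving rows, with attribute `rejections`: a named count of
#'   trajectories failing each rule (a trajectory can fail several) and the
#'   kept/total counts.
#' @export
filter_trajectories <- function(trajectories, config = tracking_config()) {
  stopifnot(inherits(config, "tracking_config"))
  if (nrow(trajectories) == 0) {
    attr(trajectories, "rejections") <-
      c(duration = 0, displacement = 0, frequency = 0, kept = 0, total = 0)
    return(trajectories)
  }
  sp <- split(seq_len(nrow(trajectories)), trajectories$trajectory)
  stats_ <- vapply(sp, function(ix) {
    o <- ix[order(trajectories$frame[ix])]
    x <- trajectories$x_mm[o]; y <- trajectories$y_mm[o]
    tt <- trajectories$time_s[o]
    n <- length(o)
    gross <- if (n > 1) sum(sqrt(diff(x)^2 + diff(y)^2)) * 1000 else 0
    dur <- tt[n] - tt[1]
    span <- trajectories$frame[o][n] - trajectories$frame[o][1] + 1L
    c(dur = dur, gross = gross, freq = n / span)
  }, c(dur = 0, gross = 0, freq = 0))
  ok_dur <- stats_["dur", ] >= config$min_duration_s
  ok_gross <- stats_["gross", ] >= config$min_gross_um
  ok_freq <- stats_["freq", ] >= config$min_detect_freq
  keep_tr <- ok_dur & ok_gross & ok_freq
  kept_ids <- as.integer(names(sp))[keep_tr]
  out <- trajectories[trajectories$trajectory %in% kept_ids, ]
  attr(out, "rejections") <- c(
    duration = sum(!ok_dur), displacement = sum(!ok_gross),
    frequency = sum(!ok_freq),
    kept = sum(keep_tr), total = length(sp)
  )
  out
}

#' Write a per-burst tracking report
#'
#' Summarises a tracked, filtered burst as JSON: detection and trajectory
#' counts plus the per-rule rejection counts from [filter_trajectories()].
#'
#' @param filtered output of [filter_trajectories()].
#' @param path file path for the JSON report.
#' @return the report list, invisibly.
#' @export
write_tracking_report <- function(filtered, path) {
  rej <- attr(filtered, "rejections")
  report <- list(
    n_detections = nrow(filtered),
    n_trajectories = length(unique(filtered$trajectory)),
    rejections = as.list(rej)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}
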