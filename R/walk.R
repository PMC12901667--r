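## Correlated random-walk stepping with specular wall reflection.
## Shared by the synthetic ground-truth generator and the null movement
## model. The hot loop lives in src/walk.cpp; an R reference implementation
## (advance_agents_r) is kept as an independent oracle for tests.

## Wall segments of a landscape as a data.frame:
##   orient "v" (x = pos, y in [lo, hi]) or "h" (y = pos, x in [lo, hi]).
## When `block_y` is given, an extra full-width horizontal wall is added at
## that y (used to suppress emigration from the Start patch during a lag).
landscape_walls <- function(spec, block_y = NULL) {
  W <- spec$patch_width
  b <- zone_breaks(spec)
  if (!spec$has_corridor) {
    w <- data.frame(
      orient = c("h", "h", "v", "v"),
      pos = c(0, b["start_hi"], 0, W),
      lo = c(0, 0, 0, 0),
      hi = c(W, W, b["start_hi"], b["start_hi"])
    )
  } else {
    cb <- corridor_band(spec)
    P <- b[["start_hi"]]; PL <- b[["corridor_hi"]]; TT <- b[["target_hi"]]
    w <- data.frame(
      orient = c("h", "h",
                 "v", "v", "v", "v",
                 "v", "v",
                 "h", "h", "h", "h"),
      pos = c(0, TT,
              0, 0, W, W,
              cb[["lo"]], cb[["hi"]],
              P, P, PL, PL),
      lo = c(0, 0,
             0, PL, 0, PL,
             P, P,
             0, cb[["hi"]], 0, cb[["hi"]]),
      hi = c(W, W,
             P, TT, P, TT,
             PL, PL,
             cb[["lo"]], W, cb[["lo"]], W)
    )
  }
  if (!is.null(block_y)) {
    w <- rbind(w, data.frame(orient = "h", pos = block_y, lo = 0, hi = W))
  }
  rownames(w) <- NULL
  w
}

## Specular reflection of the segment (x0,y0)->(x1,y1) off axis-aligned
## walls (R reference; mirrored in C++). Returns list(x, y, flip_x, flip_y).
reflect_path <- function(x0, y0, x1, y1, walls, max_bounce = 24L) {
  eps <- 1e-9
  flip_x <- FALSE; flip_y <- FALSE
  for (i in seq_len(max_bounce)) {
    dx <- x1 - x0; dy <- y1 - y0
    best_t <- Inf; best_j <- 0L
    for (j in seq_len(nrow(walls))) {
      if (walls$orient[j] == "v") {
        c0 <- walls$pos[j]
        if (abs(dx) < eps) next
        t <- (c0 - x0) / dx
        if (t <= eps || t > 1) next
        cc <- y0 + t * dy
      } else {
        c0 <- walls$pos[j]
        if (abs(dy) < eps) next
        t <- (c0 - y0) / dy
        if (t <= eps || t > 1) next
        cc <- x0 + t * dx
      }
      if (cc < walls$lo[j] - eps || cc > walls$hi[j] + eps) next
      if (t < best_t) { best_t <- t; best_j <- j }
    }
    if (best_j == 0L) break
    if (walls$orient[best_j] == "v") {
      c0 <- walls$pos[best_j]
      yc <- y0 + best_t * (y1 - y0)
      x1 <- 2 * c0 - x1
      flip_x <- !flip_x
      x0 <- c0 + sign(x0 - c0) * eps; y0 <- yc
    } else {
      c0 <- walls$pos[best_j]
      xc <- x0 + best_t * (x1 - x0)
      y1 <- 2 * c0 - y1
      flip_y <- !flip_y
      y0 <- c0 + sign(y0 - c0) * eps; x0 <- xc
    }
  }
  list(x = x1, y = y1, flip_x = flip_x, flip_y = flip_y)
}

## Geometry parameter pack consumed by the C++ stepper.
geom_pack <- function(spec, block_y = NULL) {
  cb <- if (spec$has_corridor) corridor_band(spec) else c(lo = 0, hi = 0)
  c(spec$patch_length, spec$patch_width, spec$corridor_length,
    cb[["lo"]], cb[["hi"]], as.numeric(spec$has_corridor),
    if (is.null(block_y)) NA_real_ else block_y)
}

## Advance agents by n_steps of the correlated random walk (C++ hot loop).
##
## state: list with numeric vectors x, y (mm), heading (rad).
## turn_sd: per-agent turning-angle SD for ONE step (already scaled by
## sqrt(dt / dt_ref) by the caller). One normal deviate per agent per step
## is consumed from R's RNG stream. When zone_multipliers is given, speed
## and turning SD are modulated per step by the agent's current zone.
advance_agents <- function(state, speed_um_s, turn_sd, dt, spec,
                           block_y = NULL, n_steps = 1L,
                           zone_multipliers = NULL) {
  n <- length(state$x)
  modulate <- !is.null(zone_multipliers)
  sm <- if (modulate) as.numeric(zone_multipliers$speed[.zone_levels])
        else rep(1, 4)
  tm <- if (modulate) as.numeric(zone_multipliers$turning[.zone_levels])
        else rep(1, 4)
  cpp_step_agents(state$x, state$y, state$heading,
                  rep_len(speed_um_s, n), rep_len(turn_sd, n),
                  dt, as.integer(n_steps), geom_pack(spec, block_y),
                  modulate, sm, tm)
}

## Pure-R reference stepper (single step), kept as an independent oracle:
## consumes the same RNG stream as the C++ implementation.
advance_agents_r <- function(state, speed_um_s, turn_sd, dt, spec,
                             block_y = NULL) {
  n <- length(state$x)
  walls <- landscape_walls(spec, block_y = block_y)
  heading <- state$heading + stats::rnorm(n, 0, 1) * rep_len(turn_sd, n)
  step_mm <- rep_len(speed_um_s, n) * dt / 1000
  px <- state$x + step_mm * cos(heading)
  py <- state$y + step_mm * sin(heading)
  out <- !point_in_landscape(px, py, spec)
  if (!is.null(block_y)) {
    out <- out | (state$y - block_y) * (py - block_y) < 0
  }
  for (i in which(out)) {
    r <- reflect_path(state$x[i], state$y[i], px[i], py[i], walls)
    ok <- point_in_landscape(r$x, r$y, spec) &&
      (is.null(block_y) || (state$y[i] - block_y) * (r$y - block_y) >= 0)
    if (ok) {
      px[i] <- r$x; py[i] <- r$y
      hx <- cos(heading[i]) * (if (r$flip_x) -1 else 1)
      hy <- sin(heading[i]) * (if (r$flip_y) -1 else 1)
      heading[i] <- atan2(hy, hx)
    } else {
      px[i] <- state$x[i]; py[i] <- state$y[i]
      heading[i] <- heading[i] + pi
    }
  }
  list(x = px, y = py, heading = heading)
}

## Sample initial positions uniformly in the inoculation region: a disc of
## radius `radius` mm centred at (patch_width / 2, `center_y`) intersected
## with the accessible area (the end of the Start patch opposite the
## corridor, matching inoculation through the entry points).
sample_inoculum <- function(n, spec, radius = 2, center_y = 1) {
  cx <- spec$patch_width / 2
  x <- numeric(n); y <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 16L)
    r <- radius * sqrt(stats::runif(m))
    a <- stats::runif(m, 0, 2 * pi)
    xx <- cx + r * cos(a); yy <- center_y + r * sin(a)
    ok <- point_in_landscape(xx, yy, spec)
    k <- min(sum(ok), n - got)
    if (k > 0) {
      idx <- which(ok)[seq_len(k)]
      x[(got + 1):(got + k)] <- xx[idx]
      y[(got + 1):(got + k)] <- yy[idx]
      got <- got + k
    }
  }
  list(x = x, y = y, heading = stats::runif(n, 0, 2 * pi))
}
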