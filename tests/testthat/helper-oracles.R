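# Shared fixtures and independent oracles used across test files.

# Brute-force gated assignment: among maximum-cardinality matchings of
# tracks to detections with distance <= gate, return the minimum total
# distance. Enumerates all injective maps (feasible for <= 5 x 5).
brute_force_matching <- function(tx, ty, dx, dy, gate) {
  na <- length(tx); nd <- length(dx)
  dist <- outer(tx, dx, "-")^2 + outer(ty, dy, "-")^2
  dist <- sqrt(dist)
  best <- list(card = -1L, cost = Inf, assign = rep(NA_integer_, na))
  assign <- rep(NA_integer_, na)
  recurse <- function(i, used, card, cost) {
    if (i > na) {
      if (card > best$card || (card == best$card && cost < best$cost)) {
        best <<- list(card = card, cost = cost, assign = assign)
      }
      return(invisible())
    }
    # leave track i unmatched
    recurse(i + 1, used, card, cost)
    for (j in seq_len(nd)) {
      if (!used[j] && dist[i, j] <= gate) {
        used[j] <- TRUE
        assign[i] <<- j
        recurse(i + 1, used, card + 1L, cost + dist[i, j])
        assign[i] <<- NA_integer_
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, nd), 0L, 0)
  best
}

# Total linking cost realised by link_detections on a two-frame problem.
linked_cost <- function(linked) {
  sp <- split(seq_len(nrow(linked)), linked$trajectory)
  cost <- 0; card <- 0L
  for (ix in sp) {
    if (length(ix) < 2) next
    o <- ix[order(linked$frame[ix])]
    cost <- cost + sum(sqrt(diff(linked$x_mm[o])^2 + diff(linked$y_mm[o])^2))
    card <- card + length(ix) - 1L
  }
  list(card = card, cost = cost)
}

# Detection table for cells moving deterministically (one burst).
make_moving_detections <- function(pos0, vel_mm, n_frames, dt = 1 / 7.5,
                                   time_min = 24) {
  n <- nrow(pos0)
  do.call(rbind, lapply(seq_len(n_frames), function(f) {
    data.frame(
      time_min = time_min, frame = f, time_s = time_min * 60 + (f - 1) * dt,
      x_mm = pos0[, 1] + vel_mm[, 1] * (f - 1) * dt,
      y_mm = pos0[, 2] + vel_mm[, 2] * (f - 1) * dt,
      area_um2 = 700, major_um = 40, minor_um = 25,
      source_id = seq_len(n)
    )
  }))
}

# Check that two trajectory labellings partition detections identically.
same_partition <- function(labels_a, labels_b) {
  identical(
    as.integer(factor(labels_a, levels = unique(labels_a))),
    as.integer(factor(labels_b, levels = unique(labels_b)))
  )
}

short_spec <- build_default_landscape("Short")
long_spec <- build_default_landscape("Long")
control_spec <- build_default_landscape("Control")
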