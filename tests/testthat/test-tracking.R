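test_that("detect_particles measures an ideal ellipse and applies size gates", {
  d <- data.frame(frame = 1L, x_mm = 0.6, y_mm = 0.6,
                  major_um = 50, minor_um = 25, angle_rad = 0.4)
  fr <- render_frames(d, image_shape = c(300, 300), seed = 1)
  det <- detect_particles(fr, tracking_config())
  expect_equal(nrow(det), 1)
  expect_equal(det$major_um / det$minor_um, 2.0, tolerance = 0.05)
  # area from pixel counting of a ~60-pixel ellipse: coarse quantisation
  expect_equal(det$area_um2, pi * 25 * 12.5, tolerance = 0.1)

  # blank frame: zero detections
  blank <- list(matrix(0.05, 64, 64))
  expect_equal(nrow(detect_particles(blank, tracking_config())), 0)

  # particle below the size-range minimum is excluded
  tiny <- data.frame(frame = 1L, x_mm = 0.1, y_mm = 0.1,
                     major_um = 10, minor_um = 8, angle_rad = 0)
  fr2 <- render_frames(tiny, image_shape = c(64, 64), seed = 1)
  expect_equal(nrow(detect_particles(fr2, tracking_config())), 0)
  expect_error(detect_particles(list(), tracking_config()), "empty")
})

test_that("the assignment solver matches a brute-force oracle", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(2:5, 1); m <- sample(n:6, 1)
    cost <- matrix(runif(n * m), n, m)
    sol <- microdisp:::solve_assignment(cost)
    got <- sum(cost[cbind(seq_len(n), sol)])
    # exhaustive minimum over all injective row -> column maps
    perms <- utils::combn(m, n, simplify = FALSE)
    best <- Inf
    perm_all <- function(v) {
      if (length(v) <= 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (p in perm_all(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
      out
    }
    for (cols in perms) for (p in perm_all(cols))
      best <- min(best, sum(cost[cbind(seq_len(n), p)]))
    expect_equal(got, best, tolerance = 1e-12)
    expect_false(anyDuplicated(sol) > 0)
  }
})

test_that("well-separated cells are tracked without identity switches", {
  # two cells always > max_step apart: exactly the ground-truth partition
  pos0 <- rbind(c(2, 2), c(7, 12))
  vel <- rbind(c(0.05, 0.02), c(-0.03, 0.04)) # mm/s, ~54 and 50 um/frame... scaled below
  vel <- vel / 2 # ~27 um/frame, inside the 80 um gate
  det <- make_moving_detections(pos0, vel, n_frames = 75)
  linked <- link_detections(det, tracking_config())
  expect_equal(length(unique(linked$trajectory)), 2)
  expect_true(same_partition(linked$trajectory, linked$source_id))

  # a single cell detected on all 75 frames: one trajectory of 75 detections
  one <- make_moving_detections(rbind(c(5, 5)), rbind(c(0.03, 0)), 75)
  l1 <- link_detections(one, tracking_config())
  expect_equal(length(unique(l1$trajectory)), 1)
  expect_equal(nrow(l1), 75)
})

test_that("gate-overlap assignments equal the brute-force minimum matching", {
  set.seed(202)
  cfg <- tracking_config(max_step_um = 80)
  gate <- 0.08
  for (rep in 1:30) {
    na <- sample(2:4, 1); nd <- sample(2:4, 1)
    # points packed so that gates overlap
    tx <- runif(na, 5, 5.12); ty <- runif(na, 5, 5.12)
    dx <- runif(nd, 5, 5.12); dy <- runif(nd, 5, 5.12)
    det <- rbind(
      data.frame(time_min = 24, frame = 1L, time_s = 0, x_mm = tx, y_mm = ty,
                 area_um2 = 700, major_um = 40, minor_um = 25,
                 source_id = seq_len(na)),
      data.frame(time_min = 24, frame = 2L, time_s = 1 / 7.5, x_mm = dx,
                 y_mm = dy, area_um2 = 700, major_um = 40, minor_um = 25,
                 source_id = NA)
    )
    linked <- link_detections(det, cfg)
    got <- linked_cost(linked)
    oracle <- brute_force_matching(tx, ty, dx, dy, gate)
    expect_equal(got$card, oracle$card)
    expect_equal(got$cost, oracle$cost, tolerance = 1e-9)
  }
})

test_that("every detection lands in exactly one trajectory", {
  pr <- strain_profile("S", speed_mean = 200, turning_sd = 0.4)
  sch <- burst_schedule(first_min = 1, last_min = 1, frames = 30)
  tr <- simulate_ground_truth(pr, short_spec, 80, sch, seed = 31)
  det <- detections_from_truth(tr, detection_noise(detect_prob = 0.9),
                               seed = 1, spec = short_spec)
  linked <- link_detections(det, tracking_config())
  expect_equal(nrow(linked), nrow(det))
  expect_false(anyNA(linked$trajectory))
  expect_true(all(linked$trajectory >= 1))
})

test_that("zero-noise bursts with spacing beyond the gate are recovered exactly", {
  # cells on a 2 mm grid drifting < 0.4 mm each over the burst: nearest
  # neighbours always > max_step apart, so recovery must be exact
  set.seed(41)
  g <- expand.grid(x = seq(1, 9, 2), y = seq(1, 15, 2))
  n <- nrow(g)
  vel <- matrix(runif(2 * n, -0.035, 0.035), n, 2) # mm/s: <= ~5 um/frame
  det <- make_moving_detections(as.matrix(g), vel, n_frames = 75)
  # verify the spacing precondition, then exact partition equality
  dmin <- min(vapply(1:75, function(f) {
    d <- det[det$frame == f, ]
    min(dist(cbind(d$x_mm, d$y_mm)))
  }, 1))
  expect_gt(dmin, 0.08)
  linked <- link_detections(det, tracking_config())
  expect_equal(length(unique(linked$trajectory)), n)
  expect_true(same_partition(
    linked$trajectory[order(linked$frame, linked$source_id)],
    linked$source_id[order(linked$frame, linked$source_id)]
  ))
})

test_that("a single missed frame is bridged within max_gap", {
  det <- make_moving_detections(rbind(c(5, 5)), rbind(c(0.03, 0)), 10)
  det <- det[det$frame != 5, ]
  l1 <- link_detections(det, tracking_config(max_gap = 1))
  expect_equal(length(unique(l1$trajectory)), 1)
  l0 <- link_detections(det, tracking_config(max_gap = 0))
  expect_equal(length(unique(l0$trajectory)), 2)
})

test_that("quality filters drop short, stationary and sparse trajectories", {
  cfg <- tracking_config(min_duration_s = 2, min_gross_um = 20,
                         min_detect_freq = 0.5)
  dt <- 1 / 7.5
  # stationary false-positive chain: zero gross displacement
  stationary <- make_moving_detections(rbind(c(3, 3)), rbind(c(0, 0)), 40)
  # 2-frame trajectory: duration ~0.13 s < 2 s
  short_tr <- make_moving_detections(rbind(c(8, 8)), rbind(c(0.05, 0)), 2)
  short_tr$source_id <- 2L
  # healthy trajectory present 60 of 75 frames
  healthy <- make_moving_detections(rbind(c(5, 12)), rbind(c(0.04, 0.02)), 75)
  healthy$source_id <- 3L
  healthy <- healthy[healthy$frame %% 5 != 0, ] # 60/75 frames, 1-frame gaps
  det <- rbind(stationary, short_tr, healthy)
  linked <- link_detections(det, cfg)
  kept <- filter_trajectories(linked, cfg)
  rej <- attr(kept, "rejections")
  expect_equal(unname(rej["kept"]), 1)
  expect_equal(sort(unique(kept$source_id)), 3L)
  expect_gte(unname(rej["displacement"]), 1)
  expect_gte(unname(rej["duration"]), 1)
})

test_that("tightening any filter threshold never increases survivors", {
  pr <- strain_profile("S", speed_mean = 150, turning_sd = 0.5)
  sch <- burst_schedule(first_min = 1, last_min = 1, frames = 40)
  tr <- simulate_ground_truth(pr, short_spec, 60, sch, seed = 51)
  det <- detections_from_truth(tr, detection_noise(detect_prob = 0.7,
                                                   false_positive_rate = 3),
                               seed = 2, spec = short_spec)
  linked <- link_detections(det, tracking_config())
  n_kept <- function(...) {
    cfg <- tracking_config(...)
    attr(filter_trajectories(linked, cfg), "rejections")[["kept"]]
  }
  base <- n_kept()
  expect_lte(n_kept(min_duration_s = 4), base)
  expect_lte(n_kept(min_gross_um = 100), base)
  expect_lte(n_kept(min_detect_freq = 0.9), base)
})

test_that("tracking reports serialise the filter outcome", {
  det <- make_moving_detections(rbind(c(5, 5)), rbind(c(0.04, 0)), 75)
  kept <- filter_trajectories(link_detections(det, tracking_config()),
                              tracking_config())
  path <- withr::local_tempfile(fileext = ".json")
  rep_ <- write_tracking_report(kept, path)
  expect_true(file.exists(path))
  expect_equal(rep_$n_trajectories, 1)
})
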