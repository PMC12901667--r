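test_that("swimming speed is gross displacement over duration", {
  # two detections 155 um apart, 1 s apart
  expect_equal(swimming_speed(c(0, 0.155), c(0, 0), c(0, 1)), 155)
  # square path, 4 x 100 um legs in 4 s
  sq <- list(x = c(0, 0.1, 0.1, 0, 0), y = c(0, 0, 0.1, 0.1, 0),
             t = 0:4)
  expect_equal(swimming_speed(sq$x, sq$y, sq$t), 100)
  # stationary trajectory
  expect_equal(swimming_speed(c(1, 1, 1), c(2, 2, 2), 0:2), 0)
})

test_that("linearity is net over gross displacement", {
  expect_equal(linearity(c(0, 1, 2), c(0, 0, 0)), 1.0)
  # closed square returns to start
  expect_equal(linearity(c(0, 0.1, 0.1, 0, 0), c(0, 0, 0.1, 0.1, 0)), 0.0)
  # right angle, two 100 um legs
  expect_equal(linearity(c(0, 0.1, 0.1), c(0, 0, 0.1)), sqrt(2) / 2,
               tolerance = 1e-12)
  expect_warning(v <- linearity(c(1, 1), c(2, 2)), "undefined")
  expect_true(is.na(v))
})

test_that("duration-corrected linearity removes the shortened-duration bias", {
  # straight path: invariant under windowing, any duration
  tt <- seq(0, 10, by = 1 / 7.5)
  lc <- linearity_duration_corrected(0.02 * tt, 0.01 * tt, tt)
  expect_equal(lc$value, 1.0, tolerance = 1e-12)
  expect_false(lc$fallback)

  # shorter than the reference window: falls back to raw linearity
  lc2 <- linearity_duration_corrected(c(0, 0.1), c(0, 0), c(0, 1),
                                      reference_window_s = 4)
  expect_true(lc2$fallback)
  expect_equal(lc2$value, 1.0)

  # diffusive scaling: for an unbiased random walk the corrected linearity
  # decreases as the reference window grows (net ~ sqrt(t), gross ~ t)
  set.seed(77)
  vals <- replicate(40, {
    h <- cumsum(rnorm(300, 0, 0.8))
    x <- cumsum(cos(h)) / 1000; y <- cumsum(sin(h)) / 1000
    tt <- (seq_along(x) - 1) / 7.5
    c(linearity_duration_corrected(x, y, tt, 2)$value,
      linearity_duration_corrected(x, y, tt, 8)$value)
  })
  expect_gt(mean(vals[1, ]), mean(vals[2, ]))
})

test_that("trajectory zone is the majority zone, ties toward the later zone", {
  # 3 detections in Start, 2 in Corridor -> Start
  d <- data.frame(trajectory = 1L, time_min = 24,
                  frame = 1:5, time_s = (0:4) / 7.5,
                  x_mm = c(5, 5, 5, 5, 5),
                  y_mm = c(15.7, 15.8, 15.9, 16.0, 16.1))
  d$y_mm <- c(15.7, 15.8, 15.9, 16.0, 16.1)
  rec <- trajectory_traits(d, short_spec)
  expect_equal(as.character(rec$zone), "Start")
  # 2-2 tie between Start and Corridor -> Corridor (later zone)
  d2 <- d[1:4, ]
  d2$y_mm <- c(15.8, 15.9, 16.0, 16.1)
  rec2 <- trajectory_traits(d2, short_spec)
  expect_equal(as.character(rec2$zone), "Corridor")
})

test_that("zone aggregation uses two-stage means and the >= 5 rule", {
  rec <- data.frame(
    trajectory = 1:9,
    time_min = 24,
    zone = factor(c(rep("Start", 5), rep("Corridor", 4)),
                  levels = c("Start", "Corridor", "Target", "Control")),
    n_detections = c(rep(10, 4), 75, rep(10, 4)),
    speed_um_s = c(100, 200, 150, 150, 150, 80, 90, 100, 110),
    linearity = 0.8, linearity_corrected = 0.7, linearity_fallback = FALSE,
    size_um2 = 700, shape_ratio = 1.5
  )
  agg <- aggregate_zone_traits(rec)
  start <- agg[agg$zone == "Start", ]
  corr <- agg[agg$zone == "Corridor", ]
  # trajectory-level mean, not detection-weighted
  expect_equal(start$speed_um_s, mean(c(100, 200, 150, 150, 150)))
  expect_true(start$included)
  # 4 corridor trajectories: excluded at that time point
  expect_false(corr$included)
  expect_equal(corr$n_trajectories, 4)

  # two trajectories with speeds 100 and 200 average to 150
  rec2 <- rec[1:2, ]
  rec2$speed_um_s <- c(100, 200)
  rec2$n_detections <- c(10, 90)
  expect_equal(aggregate_zone_traits(rec2)$speed_um_s, 150)
})

test_that("window averages cover t = 24 up to the half-dispersal time", {
  ser <- data.frame(
    zone = factor("Start", levels = c("Start", "Corridor", "Target", "Control")),
    time_min = c(24, 36, 48),
    n_trajectories = 10,
    speed_um_s = c(10, 20, 30),
    included = TRUE
  )
  expect_equal(window_average(ser, t_half = 36)$speed_um_s, 15)
  expect_equal(window_average(ser, t_half = 24)$speed_um_s, 10)
  ser$speed_um_s <- 42
  expect_equal(window_average(ser, t_half = 48)$speed_um_s, 42)
  expect_error(window_average(ser, t_half = 12))
})

test_that("landscape centring removes plate offsets, preserves group means", {
  # a single plate is unchanged
  v <- c(1, 2, 3)
  expect_equal(center_by_landscape(v, plate = c(1, 1, 1)), v)
  # two plates offset by a constant: offset removed, group mean preserved
  v2 <- c(1, 2, 3, 11, 12, 13)
  plate <- rep(1:2, each = 3)
  cc <- center_by_landscape(v2, plate)
  expect_equal(mean(cc), mean(v2))
  expect_equal(cc[1:3], cc[4:6])
  # group means preserved exactly with several groups
  grp <- rep(c("a", "b"), 3)
  cg <- center_by_landscape(v2, plate, grp)
  expect_equal(mean(cg[grp == "a"]), mean(v2[grp == "a"]))
  expect_equal(mean(cg[grp == "b"]), mean(v2[grp == "b"]))
})

test_that("measured per-zone speeds show no spurious syndrome for strategy none", {
  # identical true speeds: any zone difference is measurement error only
  pr <- strain_profile("S", speed_mean = 220, speed_sd = 0, turning_sd = 0.3)
  sch <- burst_schedule(first_min = 20, last_min = 40, interval_min = 10,
                        frames = 40)
  tr <- simulate_ground_truth(pr, short_spec, 150, sch, seed = 13)
  det <- detections_from_truth(tr, detection_noise(), seed = 1,
                               spec = short_spec)
  det$trajectory <- det$source_id # zero-noise identity linking
  rec <- trajectory_traits(det, short_spec)
  agg <- aggregate_zone_traits(rec)
  ok <- agg[agg$included & agg$n_trajectories >= 5, ]
  zmeans <- tapply(ok$speed_um_s, droplevels(ok$zone), mean)
  expect_true(all(abs(zmeans - 220) / 220 < 0.02))
})

test_that("the zone distribution comparison controls its type-I error", {
  # identical sampling distributions: KS rejections at about the nominal rate
  set.seed(19)
  p <- replicate(400, ks_compare(rnorm(30, 150, 30), rnorm(25, 150, 30))$p_value)
  expect_lt(mean(p < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})
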