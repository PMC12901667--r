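test_that("a zero-turning step advances exactly speed x dt along the heading", {
  st <- list(x = 5, y = 8, heading = pi / 2)
  out <- microdisp:::advance_agents(st, speed_um_s = 150, turn_sd = 0,
                                    dt = 2, spec = short_spec)
  expect_equal(out$x, 5)
  expect_equal(out$y, 8 + 150 * 2 / 1000)
  expect_equal(out$heading, pi / 2)
})

test_that("agents heading into a wall are reflected back inside", {
  # straight at the right wall of the Start patch
  st <- list(x = 9.9, y = 8, heading = 0)
  out <- microdisp:::advance_agents(st, 500, 0, 1, short_spec)
  expect_true(point_in_landscape(out$x, out$y, short_spec))
  expect_equal(out$x, 10 - (9.9 + 0.5 - 10)) # specular: overshoot mirrored
  expect_equal(cos(out$heading), -1) # x-component of the heading flipped
  # oblique reflection off the bottom wall preserves the x-component
  st2 <- list(x = 5, y = 0.1, heading = -pi / 4)
  out2 <- microdisp:::advance_agents(st2, 1000, 0, 1, short_spec)
  expect_true(point_in_landscape(out2$x, out2$y, short_spec))
  expect_gt(sin(out2$heading), 0)
  expect_equal(cos(out2$heading), cos(-pi / 4))
})

test_that("the compiled stepper matches the R reference implementation", {
  # same RNG stream: results must agree exactly, including reflections
  for (sp in list(short_spec, long_spec, control_spec)) {
    set.seed(23)
    st <- list(x = runif(80, 1, 9), y = runif(80, 0.2, 15),
               heading = runif(80, 0, 2 * pi))
    speeds <- runif(80, 100, 2000) # large steps force wall bounces
    set.seed(31)
    a <- microdisp:::advance_agents(st, speeds, 0.5, 1.5, sp)
    set.seed(31)
    b <- microdisp:::advance_agents_r(st, speeds, 0.5, 1.5, sp)
    expect_equal(a, b, tolerance = 1e-12)
    expect_true(all(point_in_landscape(a$x, a$y, sp)))
  }
  # with an emigration-blocking wall at the Start/Corridor boundary
  set.seed(7)
  st <- list(x = runif(40, 4, 6), y = runif(40, 14.5, 15.9),
             heading = rep(pi / 2, 40))
  set.seed(11)
  a <- microdisp:::advance_agents(st, 1500, 0.2, 1, short_spec, block_y = 16)
  set.seed(11)
  b <- microdisp:::advance_agents_r(st, 1500, 0.2, 1, short_spec, block_y = 16)
  expect_equal(a, b, tolerance = 1e-12)
  expect_true(all(a$y < 16))
})

test_that("turning deviates scale as sqrt(dt / dt_fine)", {
  set.seed(14)
  sigma <- 0.3; dt <- 4; dt_fine <- 1 / 7.5
  st <- list(x = rep(5, 1e4), y = rep(20, 1e4), heading = rep(0, 1e4))
  sp <- landscape_spec(1000, 1000, 1, 1, has_corridor = FALSE)
  st$x <- rep(500, 1e4); st$y <- rep(500, 1e4)
  out <- microdisp:::advance_agents(st, 100, sigma * sqrt(dt / dt_fine), dt, sp)
  turns <- out$heading - 0
  expect_equal(sd(turns), sigma * sqrt(dt / dt_fine), tolerance = 0.05)
})

test_that("turning-SD calibration reproduces the target linearity", {
  # target 1: a straight walk needs no turning
  expect_equal(calibrate_turning_sd(1), 0)
  expect_error(calibrate_turning_sd(1.2), "target_linearity")
  # self-consistency at target 0.5: re-simulated linearity within 0.01
  sig <- calibrate_turning_sd(0.5, n_rep = 2000, seed = 3)
  set.seed(99)
  n_steps <- 75
  lin <- replicate(4000, {
    h <- cumsum(rnorm(n_steps, 0, sig))
    sqrt(sum(cos(h))^2 + sum(sin(h))^2) / n_steps
  })
  expect_equal(mean(lin), 0.5, tolerance = 0.012)
  # monotonicity: straighter targets need less turning
  sigs <- vapply(c(0.3, 0.5, 0.7, 0.9), calibrate_turning_sd, 1, seed = 3)
  expect_true(all(diff(sigs) < 0))
})

test_that("the null simulation conserves agents inside the landscape", {
  cfg <- sim_config(n_agents = 250, speed_pool = c(100, 200, 400),
                    turning_sd = 0.4, snapshot_times_min = seq(12, 72, 12),
                    seed = 4)
  ns <- run_null_simulation(cfg, long_spec)
  snaps <- split(ns$snapshots, ns$snapshots$time_min)
  expect_true(all(vapply(snaps, nrow, 1L) == 250))
  expect_true(all(point_in_landscape(ns$snapshots$x_mm, ns$snapshots$y_mm,
                                     long_spec)))
  # per-agent speeds stay fixed for the whole run
  sp1 <- ns$snapshots$speed_um_s[ns$snapshots$time_min == 12]
  sp2 <- ns$snapshots$speed_um_s[ns$snapshots$time_min == 72]
  expect_identical(sp1, sp2)
})

test_that("the null simulation is seed-reproducible and validates inputs", {
  cfg <- sim_config(n_agents = 60, speed_pool = c(150), turning_sd = 0.3,
                    snapshot_times_min = c(12, 24), seed = 5)
  a <- run_null_simulation(cfg, short_spec)
  b <- run_null_simulation(cfg, short_spec)
  expect_identical(a, b)
  expect_error(sim_config(speed_pool = numeric(0)), "speed_pool")
})

test_that("snapshot metrics compute rates, front and rear correctly", {
  z <- factor(c(rep("Start", 50), rep("Corridor", 25), rep("Target", 25)),
              levels = c("Start", "Corridor", "Target", "Control"))
  snaps <- data.frame(time_min = 24, agent = 1:100,
                      x_mm = 5, y_mm = c(1:50 / 5, rep(20, 25), rep(30, 25)),
                      zone = z, speed_um_s = 100)
  m <- snapshot_metrics(snaps, short_spec)
  expect_equal(m$emigration, 0.5)
  expect_equal(m$dispersal, 0.25)
  expect_lte(m$rear_mm, m$front_mm)
  # all agents in Start: emigration and dispersal are zero
  snaps2 <- snaps
  snaps2$zone <- factor("Start", levels = levels(z))
  snaps2$y_mm <- runif(100, 0, 15)
  m2 <- snapshot_metrics(snaps2, short_spec)
  expect_equal(m2$emigration, 0)
  expect_equal(m2$dispersal, 0)
  # too few Start-patch agents: front/rear flagged as NA
  snaps3 <- snaps[c(1:5, 51:100), ]
  m3 <- snapshot_metrics(snaps3, short_spec, min_start = 10)
  expect_true(is.na(m3$rear_mm) && is.na(m3$front_mm))
})

test_that("faster agents reach the Target first (spatial sorting)", {
  cfg <- sim_config(n_agents = 1000, speed_pool = c(50, 300),
                    turning_sd = 0.2, snapshot_times_min = seq(12, 48, 12),
                    seed = 16)
  ns <- run_null_simulation(cfg, short_spec)
  sm <- snapshot_metrics(ns$snapshots, short_spec)
  tfirst <- sm$time_min[sm$n_target >= 20][1]
  expect_false(is.na(tfirst))
  tz <- ns$snapshots[ns$snapshots$time_min == tfirst &
                       ns$snapshots$zone == "Target", ]
  n_fast <- sum(tz$speed_um_s == 300)
  # two-sided binomial test against the 50/50 pool composition
  bt <- binom.test(n_fast, nrow(tz), p = 0.5)
  expect_lt(bt$p.value, 0.01)
  expect_gt(n_fast / nrow(tz), 0.5)
})
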