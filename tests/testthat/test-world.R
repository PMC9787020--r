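still_controls <- function(state) {
  list(move_dir = rep(NA_real_, 3), slow = rep(FALSE, 3),
       head = state$av_head)
}

test_that("unforced TA motion decays monotonically under drag", {
  cfg <- world_config(n_targets = 1, brownian_force_max = 0)
  state <- init_world(cfg, rng_stream(1), rng_stream(2))
  state$ta_pos <- matrix(c(250, 250), 1)
  state$ta_vel <- matrix(c(4, 3), 1)
  state$av_pos <- matrix(rep(c(50, 50), 3), 3, byrow = TRUE) # far away
  speeds <- numeric(50)
  for (i in 1:50) {
    state <- step_world(state, still_controls(state), cfg)
    speeds[i] <- sqrt(sum(state$ta_vel^2))
  }
  expect_true(all(diff(speeds) < 0))
  expect_lt(speeds[50], 4)
})

test_that("one Euler step from rest matches the hand-computed update", {
  cfg <- world_config(n_targets = 1, brownian_force_max = 0)
  state <- init_world(cfg, rng_stream(1), rng_stream(2))
  state$ta_pos <- matrix(c(255, 250), 1) # 5 m east of avatar 1
  state$ta_vel <- matrix(0, 1, 2)
  state$ta_brown <- matrix(0, 1, 2)
  state$av_pos <- rbind(c(250, 250), c(50, 50), c(60, 60)) # others far away
  s1 <- step_world(state, still_controls(state), cfg)
  dt <- 1 / cfg$physics_hz
  # F = 450/5 = 90 N along +x; v1 = F/m * dt; x1 = x0 + v1 * dt
  expect_equal(s1$ta_vel, matrix(c(90 * dt, 0), 1), tolerance = 1e-12)
  expect_equal(s1$ta_pos[1, 1], 255 + 90 * dt^2, tolerance = 1e-12)
  # acceleration direction is the unit vector from avatar to TA
  expect_equal(s1$ta_vel[1, ] / sqrt(sum(s1$ta_vel^2)), c(1, 0))
})

test_that("TA speeds never exceed the 10 m/s cap under any forcing", {
  cfg <- world_config(n_targets = 5)
  state <- init_world(cfg, rng_stream(3), rng_stream(4))
  # park the avatars on top of the flock to maximize repulsion
  state$av_pos <- state$ta_pos[1:3, ] + 0.5
  set.seed(7)
  max_speed <- 0
  for (i in 1:2000) {
    if (i %% 90 == 1) {
      state$ta_brown <- sample_brownian_force(5, cfg$brownian_force_max)
    }
    ctl <- list(move_dir = runif(3, -pi, pi), slow = rep(FALSE, 3),
                head = state$av_head)
    state <- step_world(state, ctl, cfg)
    max_speed <- max(max_speed, sqrt(rowSums(state$ta_vel^2)))
  }
  expect_lte(max_speed, cfg$ta_speed_max + 1e-9)
})

test_that("status rules: containment, fleeing, and the all-contained flip", {
  cfg <- world_config(n_targets = 3)
  state <- init_world(cfg, rng_stream(5), rng_stream(6))
  ctr <- cfg$containment_center
  # all TAs strictly inside: every status flips to all_contained
  state$ta_pos <- rbind(ctr, ctr + c(1, 0), ctr + c(0, 2))
  state <- update_statuses(state, cfg)
  expect_true(all(state$ta_status == TA_STATUS[["all_contained"]]))
  # boundary is closed: distance exactly diameter/2 counts as contained
  state$ta_pos <- rbind(ctr + c(5, 0), ctr + c(100, 0), ctr + c(0, 150))
  state$av_pos <- matrix(rep(ctr + c(300, 0), 3), 3, byrow = TRUE)
  state <- update_statuses(state, cfg)
  expect_identical(state$ta_status[1], TA_STATUS[["contained"]])
  expect_identical(state$ta_status[2], TA_STATUS[["idle"]])
  # an avatar within 9.9 m makes an uncontained TA flee
  state$av_pos[1, ] <- ctr + c(100 + 9.9, 0)
  state <- update_statuses(state, cfg)
  expect_identical(state$ta_status[2], TA_STATUS[["fleeing"]])
  # containment takes precedence over fleeing
  state$av_pos[1, ] <- ctr + c(6, 0) # within 10 m of the contained TA
  state <- update_statuses(state, cfg)
  expect_identical(state$ta_status[1], TA_STATUS[["contained"]])
})

test_that("spawns respect the radii and are area-uniform over the disc", {
  cfg <- world_config()
  ctr <- cfg$containment_center
  d_av <- c()
  d_ta <- c()
  for (s in 1:250) {
    st <- init_world(cfg, rng_stream(1000 + s), rng_stream(2000 + s))
    d_av <- c(d_av, sqrt(rowSums(sweep(st$av_pos, 2, ctr)^2)))
    d_ta <- c(d_ta, sqrt(rowSums(sweep(st$ta_pos, 2, ctr)^2)))
  }
  expect_true(all(d_av <= cfg$player_spawn_radius))
  expect_true(all(d_ta <= cfg$ta_spawn_radius))
  # area-uniform sampling makes (r/R)^2 uniform on [0, 1]
  expect_gt(ks.test((d_av / cfg$player_spawn_radius)^2, "punif")$p.value, 0.01)
  expect_gt(ks.test((d_ta / cfg$ta_spawn_radius)^2, "punif")$p.value, 0.01)
})
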