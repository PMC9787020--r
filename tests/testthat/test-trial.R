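test_that("identical config and seed give bit-identical trial logs", {
  cfg <- world_config(n_targets = 3, trial_max = 15)
  pol <- replicate(3, policy_config(strategy = "corral_nearest"),
                   simplify = FALSE)
  a <- run_trial(cfg, pol, seed = 404)
  b <- run_trial(cfg, pol, seed = 404)
  expect_identical(a, b)
  c <- run_trial(cfg, pol, seed = 405)
  expect_false(identical(a$ta_x, c$ta_x))
})

test_that("a guarded hold ends the trial success_hold seconds after first containment", {
  cfg <- world_config(n_targets = 3, brownian_force_max = 0, trial_max = 60)
  ctr <- cfg$containment_center
  # TAs start inside the containment area, avatars guard from outside;
  # without Brownian forcing nothing can escape
  init <- list(
    ta_pos = rbind(ctr + c(1, 0), ctr + c(-1, 1), ctr + c(0, -2)),
    av_pos = rbind(ctr + c(14, 0), ctr + c(-7, 12), ctr + c(-7, -12))
  )
  pol <- replicate(3, policy_config(strategy = "corral_nearest"),
                   simplify = FALSE)
  tr <- run_trial(cfg, pol, seed = 1, init = init)
  dt <- 1 / cfg$physics_hz
  expect_identical(tr$outcome, "success")
  # first all-contained instant is the first step
  expect_equal(tr$duration, dt + cfg$success_hold, tolerance = 2 * dt)
})

test_that("an exit during the hold resets the success timer", {
  # a lone Brownian TA wanders across the containment boundary while the
  # avatars are parked far away and effectively immobile; under this seed
  # the TA accumulates over 5 s of total containment but never 5 s
  # continuously, so a cumulative timer would (wrongly) declare success
  cfg <- world_config(n_targets = 1, trial_max = 60,
                      avatar_speed = 1e-6, avatar_speed_slow = 1e-7)
  ctr <- cfg$containment_center
  pol <- replicate(3, policy_config(strategy = "random_walk",
                                    global_info = FALSE, sense_radius = 10),
                   simplify = FALSE)
  tr <- run_trial(cfg, pol, seed = 3, init = list(
    ta_pos = matrix(ctr + c(4.9, 0), 1),
    av_pos = rbind(ctr + c(200, 0), ctr + c(210, 0), ctr + c(220, 0))
  ))
  d <- sqrt((tr$ta_x - ctr[1])^2 + (tr$ta_y - ctr[2])^2)
  contained <- as.vector(d <= cfg$containment_diameter / 2)
  runs <- rle(contained)
  hold_frames <- cfg$success_hold * cfg$physics_hz
  expect_gt(sum(contained), hold_frames) # cumulative containment > 5 s
  expect_lt(max(runs$lengths[runs$values]), hold_frames) # no 5 s run
  expect_identical(tr$outcome, "fail")
  expect_identical(tr$duration, cfg$trial_max)
})

test_that("immobile teams fail at exactly the trial ceiling", {
  cfg <- world_config(n_targets = 2, brownian_force_max = 0, trial_max = 20,
                      avatar_speed = 1e-6, avatar_speed_slow = 1e-7)
  pol <- replicate(3, policy_config(strategy = "random_walk",
                                    global_info = FALSE, sense_radius = 10),
                   simplify = FALSE)
  tr <- run_trial(cfg, pol, seed = 3)
  expect_identical(tr$outcome, "fail")
  expect_identical(tr$duration, cfg$trial_max)
  expect_equal(nrow(tr$player_x), cfg$trial_max * cfg$log_hz)
})

test_that("logged kinematics respect both speed caps", {
  tr <- full_fail_trial()
  cfg <- tr$config
  dt <- 1 / cfg$log_hz
  ta_step <- sqrt(diff(tr$ta_x)^2 + diff(tr$ta_y)^2)
  expect_lte(max(ta_step), cfg$ta_speed_max * dt + 1e-9)
  av_step <- sqrt(diff(tr$player_x)^2 + diff(tr$player_y)^2)
  expect_lte(max(av_step), cfg$avatar_speed * dt + 1e-9)
})

test_that("invalid trial inputs are rejected before simulation", {
  cfg <- world_config(n_targets = 2, trial_max = 10)
  pol <- replicate(3, policy_config(), simplify = FALSE)
  expect_error(run_trial(cfg, pol[1:2], seed = 1), "three")
  expect_error(run_trial(unclass(cfg), pol, seed = 1))
  bad <- cfg
  bad$trial_max <- -5
  expect_error(run_trial(bad, pol, seed = 1), "trial_max")
})
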