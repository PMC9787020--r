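make_state <- function(cfg, ta_pos, av_pos) {
  n <- nrow(ta_pos)
  update_statuses(list(
    ta_pos = ta_pos, ta_vel = matrix(0, n, 2),
    ta_brown = matrix(0, n, 2),
    ta_status = rep(TA_STATUS[["idle"]], n),
    av_pos = av_pos, av_head = rep(0, 3), av_slow = rep(FALSE, 3),
    t = 0
  ), cfg)
}

test_that("global observations carry the full world, local ones are masked", {
  cfg <- world_config(n_targets = 6)
  ctr <- cfg$containment_center
  ta <- sweep(matrix(c(50, 0, -60, 10, 0, 70, 5, 5, -3, 1, 120, -40),
                     ncol = 2, byrow = TRUE), 2, ctr, `+`)
  av <- rbind(ctr + c(1, 0), ctr + c(200, 0), ctr + c(-200, 0))
  st <- make_state(cfg, ta, av)

  ob_g <- policy_observe(st, policy_config(global_info = TRUE), 1, cfg)
  expect_length(ob_g$tas$idx, 6)
  expect_length(ob_g$players$idx, 2)

  ob_l <- policy_observe(st, policy_config(global_info = FALSE,
                                           sense_radius = 10), 1, cfg)
  # only the two TAs within 10 m of player 1 (at the center)
  expect_setequal(ob_l$tas$idx, c(4, 5))
  expect_null(ob_l$players)
  # the containment landmark is available in both conditions
  expect_equal(ob_l$containment$center, ctr)
  expect_equal(ob_g$containment$distance, 1)
})

test_that("fog reduces the number of visible TAs across a logged trial", {
  tr <- small_trial()
  cfg <- tr$config
  fog <- policy_config(global_info = FALSE, sense_radius = 10)
  clear <- policy_config(global_info = FALSE, sense_radius = 150)
  n_fog <- n_clear <- numeric(0)
  idx <- seq(1, nrow(tr$player_x), by = 30)
  for (i in idx) {
    st <- make_state(cfg, cbind(tr$ta_x[i, ], tr$ta_y[i, ]),
                     cbind(tr$player_x[i, ], tr$player_y[i, ]))
    n_fog <- c(n_fog, length(policy_observe(st, fog, 1, cfg)$tas$idx))
    n_clear <- c(n_clear, length(policy_observe(st, clear, 1, cfg)$tas$idx))
  }
  expect_lt(mean(n_fog), mean(n_clear))
})

test_that("random search directions are uniform over fresh draws", {
  cfg <- world_config(n_targets = 1)
  ctr <- cfg$containment_center
  pol <- policy_config(strategy = "random_walk", global_info = FALSE,
                       sense_radius = 10)
  st <- make_state(cfg, matrix(ctr + c(170, 0), 1),
                   rbind(ctr, ctr + c(300, 300), ctr + c(-300, 300)))
  ob <- policy_observe(st, pol, 1, cfg)
  dirs <- vapply(1:1000, function(k) {
    ps <- policy_init(1, pol, rng_stream(k), rng_stream(k + 5000))
    policy_act(ob, ps, pol, cfg)$move_dir
  }, numeric(1))
  # circular resultant of uniform directions is near zero
  expect_lt(sqrt(mean(cos(dirs))^2 + mean(sin(dirs))^2), 0.08)
})

test_that("corralling targets the far side of the TA from containment", {
  cfg <- world_config(n_targets = 1)
  ctr <- cfg$containment_center
  theta <- 0.7
  ta <- ctr + 80 * c(cos(theta), sin(theta))
  pol <- policy_config(strategy = "corral_nearest")
  st <- make_state(cfg, matrix(ta, 1),
                   rbind(ctr + c(-50, 0), ctr + c(-60, 10), ctr + c(-60, -10)))
  ob <- policy_observe(st, pol, 1, cfg)
  ps <- policy_init(1, pol, rng_stream(1), rng_stream(2))
  ctl <- policy_act(ob, ps, pol, cfg)
  # commanded point lies beyond the TA on the ray from containment through it
  rel <- ctl$target - ctr
  expect_equal(atan2(rel[2], rel[1]), theta, tolerance = 1e-6)
  expect_gt(sqrt(sum(rel^2)), 80)
})

test_that("degenerate scan makes head orientation equal movement heading", {
  cfg <- world_config(n_targets = 1)
  ctr <- cfg$containment_center
  pol <- policy_config(strategy = "corral_nearest", scan_amplitude = 0,
                       heading_noise_sd = 0)
  st <- make_state(cfg, matrix(ctr + c(100, 30), 1),
                   rbind(ctr + c(-40, 0), ctr + c(-50, 10), ctr + c(-50, -10)))
  ob <- policy_observe(st, pol, 1, cfg)
  ps <- policy_init(1, pol, rng_stream(1), rng_stream(2))
  ctl <- policy_act(ob, ps, pol, cfg)
  expect_false(is.na(ctl$move_dir))
  expect_identical(ctl$head, ctl$move_dir)
})
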