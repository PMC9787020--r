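#' Run one seeded trial of the herding task
#'
#' Simulates the full loop at `physics_hz`: scripted policies recompute
#' controls at their `control_hz`, Brownian forces are resampled at
#' `brownian_rate`, and the world state is logged at `log_hz`. The trial
#' succeeds (and ends) as soon as all TAs have been continuously contained
#' for `success_hold` seconds — any single-frame exit resets the hold timer —
#' and otherwise fails at `trial_max` with `duration = trial_max`. Given the
#' same `(config, policies, seed)` the trial log is bit-identical: spawning,
#' Brownian kicks, and each policy draw from independent substreams derived
#' from `seed`.
#'
#' @param config A [world_config()].
#' @param policies List of exactly three [policy_config()] objects.
#' @param seed Integer trial seed.
#' @param init Optional list overriding initial state: any of `ta_pos`
#'   (n x 2), `av_pos` (3 x 2). Used to construct specific scenarios.
#' @return A `herd_trial_log` object: logged tracks (`time`, `player_x/y`,
#'   `player_head`, `ta_x/y`, `ta_status`), `outcome` (`"success"` or
#'   `"fail"`), `duration` in seconds, condition labels, and provenance
#'   (`config`, `policies`, `seed`).
#' @export
run_trial <- function(config, policies, seed, init = NULL) {
  if (!inherits(config, "herd_world_config")) {
    stop("run_trial: `config` must be a world_config object", call. = FALSE)
  }
  validate_world_config(config)
  if (!is.list(policies) || length(policies) != 3L ||
      !all(vapply(policies, inherits, logical(1L), "herd_policy_config"))) {
    stop("run_trial: `policies` must be a list of three policy_config objects",
         call. = FALSE)
  }
  seed <- as.integer(seed)

  spawn_stream <- rng_stream(derive_seed(seed, 1L))
  brown_stream <- rng_stream(derive_seed(seed, 2L))
  pstates <- vector("list", 3L)
  for (i in 1:3) {
    # shared_sweep players hold separate streams with the same seed, so
    # each walks the identical waypoint route at its own pace
    wp <- if (policies[[i]]$strategy == "shared_sweep") {
      rng_stream(derive_seed(seed, 99L))
    } else {
      rng_stream(derive_seed(seed, 10L + i))
    }
    pstates[[i]] <- policy_init(i, policies[[i]],
                                wp_stream = wp,
                                noise_stream = rng_stream(derive_seed(seed, 20L + i)))
  }

  state <- init_world(config, spawn_stream, brown_stream)
  if (!is.null(init)) {
    if (!is.null(init$ta_pos)) {
      stopifnot(nrow(init$ta_pos) == config$n_targets)
      state$ta_pos <- matrix(as.numeric(init$ta_pos), ncol = 2L)
    }
    if (!is.null(init$av_pos)) {
      stopifnot(nrow(init$av_pos) == 3L)
      state$av_pos <- matrix(as.numeric(init$av_pos), ncol = 2L)
    }
    state <- update_statuses(state, config)
  }

  n_steps <- as.integer(round(config$trial_max * config$physics_hz))
  log_every <- as.integer(config$physics_hz / config$log_hz)
  brown_every <- max(1L, as.integer(round(config$physics_hz / config$brownian_rate)))
  ctrl_every <- vapply(policies, function(p) {
    max(1L, as.integer(round(config$physics_hz / p$control_hz)))
  }, integer(1L))
  hold_needed <- as.integer(round(config$success_hold * config$physics_hz))

  n_log_max <- n_steps %/% log_every
  k <- config$n_targets
  log_time <- numeric(n_log_max)
  log_px <- matrix(NA_real_, n_log_max, 3L)
  log_py <- matrix(NA_real_, n_log_max, 3L)
  log_ph <- matrix(NA_real_, n_log_max, 3L)
  log_tx <- matrix(NA_real_, n_log_max, k)
  log_ty <- matrix(NA_real_, n_log_max, k)
  log_ts <- matrix(NA_integer_, n_log_max, k)

  move_dir <- rep(NA_real_, 3L)
  slow <- rep(FALSE, 3L)
  head_ang <- state$av_head
  hold <- 0L
  outcome <- "fail"
  duration <- config$trial_max
  row <- 0L

  for (s in seq_len(n_steps)) {
    if (s > 1L && (s - 1L) %% brown_every == 0L) {
      state$ta_brown <- stream_do(brown_stream, sample_brownian_force,
                                  k, config$brownian_force_max)
    }
    for (i in 1:3) {
      if ((s - 1L) %% ctrl_every[i] == 0L) {
        obs <- policy_observe(state, policies[[i]], i, config)
        ctl <- policy_act(obs, pstates[[i]], policies[[i]], config)
        move_dir[i] <- ctl$move_dir
        slow[i] <- ctl$slow
        head_ang[i] <- ctl$head
      }
    }
    state <- step_world(state,
                        list(move_dir = move_dir, slow = slow, head = head_ang),
                        config)
    if (s %% log_every == 0L) {
      row <- row + 1L
      log_time[row] <- state$t
      log_px[row, ] <- state$av_pos[, 1L]
      log_py[row, ] <- state$av_pos[, 2L]
      log_ph[row, ] <- state$av_head
      log_tx[row, ] <- state$ta_pos[, 1L]
      log_ty[row, ] <- state$ta_pos[, 2L]
      log_ts[row, ] <- state$ta_status
    }
    if (state$ta_status[1L] == TA_STATUS[["all_contained"]]) {
      hold <- hold + 1L
      if (hold >= hold_needed) {
        outcome <- "success"
        duration <- state$t
        break
      }
    } else {
      hold <- 0L
    }
  }

  keep <- seq_len(row)
  structure(list(
    sample_rate = config$log_hz,
    time = log_time[keep],
    player_x = log_px[keep, , drop = FALSE],
    player_y = log_py[keep, , drop = FALSE],
    player_head = log_ph[keep, , drop = FALSE],
    ta_x = log_tx[keep, , drop = FALSE],
    ta_y = log_ty[keep, , drop = FALSE],
    ta_status = log_ts[keep, , drop = FALSE],
    outcome = outcome,
    duration = duration,
    condition = list(
      n_targets = k,
      sense_radius = vapply(policies, `[[`, numeric(1L), "sense_radius"),
      global_info = vapply(policies, `[[`, logical(1L), "global_info"),
      strategy = vapply(policies, `[[`, character(1L), "strategy")
    ),
    config = config,
    policies = policies,
    seed = seed
  ), class = "herd_trial_log")
}

#' @export
print.herd_trial_log <- function(x, ...) {
  cat("<herd_trial_log> ", nrow(x$player_x), " samples at ", x$sample_rate,
      " Hz | ", ncol(x$ta_x), " TAs | outcome: ", x$outcome,
      " | duration: ", format(x$duration, digits = 4), " s | seed: ",
      x$seed, "\n", sep = "")
  invisible(x)
}
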