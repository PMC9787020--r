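# World state is a plain list:
#   ta_pos, ta_vel, ta_brown : n_targets x 2 matrices (m, m/s, N)
#   ta_status                : integer vector (see status codes below)
#   av_pos                   : 3 x 2 matrix (m)
#   av_head                  : numeric(3), radians in (-pi, pi]
#   av_slow                  : logical(3)
#   t                        : simulated time (s)

#' TA status codes
#'
#' Integer codes mirroring the ring-light colors of the original game:
#' `idle` (orange, unperturbed), `fleeing` (red, an avatar within the
#' repulsion radius), `contained` (blue, inside the containment area), and
#' `all_contained` (green, every TA contained). Containment takes precedence
#' over fleeing.
#'
#' @format Named integer vector.
#' @export
TA_STATUS <- c(idle = 0L, fleeing = 1L, contained = 2L, all_contained = 3L)

#' @rdname TA_STATUS
#' @param code Integer status codes.
#' @return `status_label()` returns the corresponding character labels.
#' @export
status_label <- function(code) names(TA_STATUS)[match(code, TA_STATUS)]

#' Sample positions uniformly over a disc
#'
#' Area-uniform sampling (`r = R * sqrt(u)`) used for both avatar and TA
#' spawning; draws from the current RNG state.
#'
#' @param n Number of points.
#' @param center Disc center `c(x, y)`.
#' @param radius Disc radius.
#' @return An `n x 2` matrix.
#' @export
spawn_disc <- function(n, center, radius) {
  r <- radius * sqrt(runif(n))
  a <- runif(n, 0, 2 * pi)
  cbind(center[1L] + r * cos(a), center[2L] + r * sin(a))
}

#' Initialize a world state
#'
#' Spawns avatars within `player_spawn_radius` and TAs within
#' `ta_spawn_radius` of the containment center (area-uniform, no exclusion
#' zone), zero TA velocities, a first Brownian force sample per TA, and
#' avatar headings facing the containment area.
#'
#' @param config A [world_config()].
#' @param spawn_stream,brown_stream RNG substreams (see [derive_seed()]);
#'   when `NULL`, draws come from the current RNG state.
#' @return A world-state list.
#' @export
init_world <- function(config, spawn_stream = NULL, brown_stream = NULL) {
  ctr <- config$containment_center
  draw_spawn <- function() {
    list(
      av = spawn_disc(3L, ctr, config$player_spawn_radius),
      ta = spawn_disc(config$n_targets, ctr, config$ta_spawn_radius)
    )
  }
  sp <- if (is.null(spawn_stream)) draw_spawn() else stream_do(spawn_stream, draw_spawn)
  draw_brown <- function() {
    sample_brownian_force(config$n_targets, config$brownian_force_max)
  }
  brown <- if (is.null(brown_stream)) draw_brown() else stream_do(brown_stream, draw_brown)
  state <- list(
    ta_pos = sp$ta,
    ta_vel = matrix(0, config$n_targets, 2L),
    ta_brown = brown,
    ta_status = rep(TA_STATUS[["idle"]], config$n_targets),
    av_pos = sp$av,
    av_head = atan2(ctr[2L] - sp$av[, 2L], ctr[1L] - sp$av[, 1L]),
    av_slow = rep(FALSE, 3L),
    t = 0
  )
  update_statuses(state, config)
}

#' Advance the world by one physics step
#'
#' Semi-implicit Euler integration at `dt = 1 / physics_hz`: TA velocities
#' are updated from the currently held Brownian force, the summed repulsive
#' forces of all avatars within the repulsion radius, and linear drag
#' `-gamma * v`; speeds are then capped at `ta_speed_max` by rescaling, and
#' positions advanced with the new velocity. Avatars move kinematically at
#' `avatar_speed` (or `avatar_speed_slow`) along their commanded direction.
#' All positions are clamped to the arena, zeroing the outward velocity
#' component of any TA at a wall. Brownian forces are *held*, not resampled,
#' here; the trial loop resamples them at `brownian_rate` (see
#' [run_trial()]).
#'
#' @param state World-state list (see [init_world()]).
#' @param controls List with `move_dir` (numeric(3), radians; `NA` = stay),
#'   `slow` (logical(3)), and `head` (numeric(3), radians).
#' @param config A [world_config()].
#' @return The advanced world state, with statuses updated.
#' @export
step_world <- function(state, controls, config) {
  dt <- 1 / config$physics_hz
  n <- nrow(state$ta_pos)

  force <- state$ta_brown
  for (i in 1:3) {
    dxy <- state$ta_pos - matrix(state$av_pos[i, ], n, 2L, byrow = TRUE)
    d2 <- dxy[, 1L]^2 + dxy[, 2L]^2
    near <- d2 <= config$repulsion_radius^2
    if (any(near)) {
      sub <- dxy[near, , drop = FALSE]
      d <- sqrt(d2[near])
      mag <- pmin(config$repulsion_force_max, config$repulsion_force_max / d)
      bad <- d == 0
      if (any(bad)) { # coincident avatar/TA: cap magnitude, push along +x
        sub[bad, 1L] <- 1
        sub[bad, 2L] <- 0
        d[bad] <- 1
        mag[bad] <- config$repulsion_force_max
      }
      force[near, ] <- force[near, , drop = FALSE] + (mag / d) * sub
    }
  }

  vel <- state$ta_vel +
    dt * (force / config$ta_mass - config$drag_coefficient * state$ta_vel)
  spd2 <- vel[, 1L]^2 + vel[, 2L]^2
  over <- spd2 > config$ta_speed_max^2
  if (any(over)) {
    vel[over, ] <- vel[over, , drop = FALSE] *
      (config$ta_speed_max / sqrt(spd2[over]))
  }
  pos <- state$ta_pos + dt * vel

  side <- config$arena_side
  lo <- pos < 0
  hi <- pos > side
  if (any(lo) || any(hi)) {
    vel[lo & vel < 0] <- 0
    vel[hi & vel > 0] <- 0
    pos[lo] <- 0
    pos[hi] <- side
  }
  if (anyNA(pos) || anyNA(vel)) {
    stop("step_world: non-finite TA state at t = ", state$t, call. = FALSE)
  }

  mv <- controls$move_dir
  speed <- rep.int(config$avatar_speed, 3L)
  speed[controls$slow] <- config$avatar_speed_slow
  moving <- !is.na(mv)
  av <- state$av_pos
  if (any(moving)) {
    av[moving, 1L] <- av[moving, 1L] + dt * speed[moving] * cos(mv[moving])
    av[moving, 2L] <- av[moving, 2L] + dt * speed[moving] * sin(mv[moving])
    av[av < 0] <- 0
    av[av > side] <- side
  }

  state$ta_pos <- pos
  state$ta_vel <- vel
  state$av_pos <- av
  state$av_head <- wrap_angle(controls$head)
  state$av_slow <- as.logical(controls$slow)
  state$t <- state$t + dt
  update_statuses(state, config)
}

#' Recompute TA ring-light statuses
#'
#' A TA is `contained` when its center lies inside the closed containment
#' disc (distance from center `<= containment_diameter / 2`); `fleeing` when
#' uncontained with any avatar within the repulsion radius; `all_contained`
#' replaces `contained` when every TA is contained; otherwise `idle`.
#'
#' @inheritParams step_world
#' @return The state with `ta_status` updated.
#' @export
update_statuses <- function(state, config) {
  ctr <- config$containment_center
  dx <- state$ta_pos[, 1L] - ctr[1L]
  dy <- state$ta_pos[, 2L] - ctr[2L]
  contained <- dx * dx + dy * dy <= (config$containment_diameter / 2)^2
  n <- nrow(state$ta_pos)
  near_av <- rep(FALSE, n)
  r2 <- config$repulsion_radius^2
  for (i in 1:3) {
    ax <- state$ta_pos[, 1L] - state$av_pos[i, 1L]
    ay <- state$ta_pos[, 2L] - state$av_pos[i, 2L]
    near_av <- near_av | (ax * ax + ay * ay <= r2)
  }
  status <- rep(TA_STATUS[["idle"]], n)
  status[near_av] <- TA_STATUS[["fleeing"]]
  status[contained] <- TA_STATUS[["contained"]]
  if (all(contained)) status[] <- TA_STATUS[["all_contained"]]
  state$ta_status <- status
  state
}

# wrap to (-pi, pi]
wrap_angle <- function(a) {
  w <- atan2(sin(a), cos(a))
  w[w == -pi] <- pi
  w
}
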