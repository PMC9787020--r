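#' World configuration for the herding task
#'
#' Physics, arena, and trial parameters of the headless herding environment.
#' Defaults reproduce the study conditions of the original game server: a
#' 500 x 500 m arena with a 10 m diameter central containment area, target
#' agents (TAs) of 1 kg driven by a uniform random force of 0-60 N resampled
#' at 1 Hz, a repulsive force from any avatar within 10 m that is inversely
#' proportional to distance and capped at 450 N, TA speeds capped at 10 m/s,
#' avatars moving at 10 m/s (5 m/s in slow mode), spawn radii of 100 m
#' (avatars) and 180 m (TAs) around the containment area, a 300 s trial cap,
#' success after 5 continuous seconds of full containment, and 90 Hz
#' simulation/logging.
#'
#' @param arena_side Arena side length in meters.
#' @param containment_center Containment-area center `(x, y)` in meters;
#'   defaults to the arena center.
#' @param containment_diameter Containment-area diameter in meters.
#' @param n_targets Number of target agents (the study used 9 or 18).
#' @param ta_mass TA mass in kg.
#' @param brownian_force_max Upper bound of the uniform random force, N.
#' @param brownian_rate Resampling rate of the random force, Hz.
#' @param repulsion_radius Avatar-TA interaction radius, m.
#' @param repulsion_force_max Cap on the repulsive force, N.
#' @param ta_speed_max TA speed cap, m/s.
#' @param avatar_speed Avatar speed, m/s.
#' @param avatar_speed_slow Avatar speed in slow (fine-control) mode, m/s.
#' @param player_spawn_radius Avatar spawn radius around containment, m.
#' @param ta_spawn_radius TA spawn radius around containment, m.
#' @param trial_max Maximum trial duration, s.
#' @param success_hold Continuous full-containment time required for
#'   success, s.
#' @param physics_hz Fixed integration rate, Hz.
#' @param log_hz Logging rate, Hz (must divide `physics_hz`).
#' @param drag_coefficient Linear drag coefficient gamma in 1/s; the TA force
#'   balance is `brownian + repulsion - gamma * m * velocity`. The original
#'   game engine applies drag implicitly and does not document its value; it
#'   is an explicit knob here. The default of 20 gives roaming speeds of
#'   about 1.5 m/s (3 m/s peak) under the 0-60 N Brownian kicks, which makes
#'   unperturbed TAs wander diffusively and makes the 5 s containment hold
#'   attainable by a competent team, while repulsion at close range still
#'   drives TAs at up to the 10 m/s cap. With values near 1 the Brownian
#'   kicks alone drive every TA at the speed cap and no team, scripted or
#'   human, can hold the containment area.
#' @return An object of class `herd_world_config` (a validated list).
#' @export
world_config <- function(arena_side = 500,
                         containment_center = c(arena_side / 2, arena_side / 2),
                         containment_diameter = 10,
                         n_targets = 9,
                         ta_mass = 1,
                         brownian_force_max = 60,
                         brownian_rate = 1,
                         repulsion_radius = 10,
                         repulsion_force_max = 450,
                         ta_speed_max = 10,
                         avatar_speed = 10,
                         avatar_speed_slow = 5,
                         player_spawn_radius = 100,
                         ta_spawn_radius = 180,
                         trial_max = 300,
                         success_hold = 5,
                         physics_hz = 90,
                         log_hz = 90,
                         drag_coefficient = 20) {
  cfg <- list(
    arena_side = arena_side,
    containment_center = as.numeric(containment_center),
    containment_diameter = containment_diameter,
    n_targets = as.integer(n_targets),
    ta_mass = ta_mass,
    brownian_force_max = brownian_force_max,
    brownian_rate = brownian_rate,
    repulsion_radius = repulsion_radius,
    repulsion_force_max = repulsion_force_max,
    ta_speed_max = ta_speed_max,
    avatar_speed = avatar_speed,
    avatar_speed_slow = avatar_speed_slow,
    player_spawn_radius = player_spawn_radius,
    ta_spawn_radius = ta_spawn_radius,
    trial_max = trial_max,
    success_hold = success_hold,
    physics_hz = physics_hz,
    log_hz = log_hz,
    drag_coefficient = drag_coefficient
  )
  class(cfg) <- "herd_world_config"
  validate_world_config(cfg)
  cfg
}

validate_world_config <- function(cfg) {
  pos <- c(
    "arena_side", "containment_diameter", "ta_mass", "brownian_rate",
    "repulsion_radius", "repulsion_force_max", "ta_speed_max",
    "avatar_speed", "avatar_speed_slow", "player_spawn_radius",
    "ta_spawn_radius", "trial_max", "success_hold", "physics_hz", "log_hz"
  )
  for (f in pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("world_config: `", f, "` must be a single positive finite number",
           call. = FALSE)
    }
  }
  if (cfg$brownian_force_max < 0 || !is.finite(cfg$brownian_force_max)) {
    stop("world_config: `brownian_force_max` must be finite and >= 0",
         call. = FALSE)
  }
  if (cfg$n_targets < 1L) {
    stop("world_config: `n_targets` must be at least 1", call. = FALSE)
  }
  if (length(cfg$containment_center) != 2L ||
      any(!is.finite(cfg$containment_center))) {
    stop("world_config: `containment_center` must be finite (x, y)",
         call. = FALSE)
  }
  if (cfg$avatar_speed_slow >= cfg$avatar_speed) {
    stop("world_config: `avatar_speed_slow` must be < `avatar_speed`",
         call. = FALSE)
  }
  if (cfg$success_hold >= cfg$trial_max) {
    stop("world_config: `success_hold` must be < `trial_max`", call. = FALSE)
  }
  if (cfg$containment_diameter >= cfg$ta_spawn_radius) {
    stop("world_config: `containment_diameter` must be < `ta_spawn_radius`",
         call. = FALSE)
  }
  if (cfg$drag_coefficient < 0) {
    stop("world_config: `drag_coefficient` must be >= 0", call. = FALSE)
  }
  if (cfg$physics_hz %% cfg$log_hz != 0) {
    stop("world_config: `log_hz` must divide `physics_hz`", call. = FALSE)
  }
  invisible(cfg)
}

#' Scripted-player policy configuration
#'
#' Sensing and strategy parameters of one scripted player. The sensing
#' parameters emulate the original task manipulations: `sense_radius = 10`
#' emulates dense fog (clear sight limited to about 10 m), `sense_radius >=
#' 150` emulates clear visibility; `global_info = TRUE` emulates the HUD that
#' displayed the positions, headings, and statuses of all avatars and TAs,
#' `FALSE` the compass that conveyed only the player's own heading plus the
#' containment-area landmark.
#'
#' @param strategy Search strategy: `"partitioned_sweep"` (each player sweeps
#'   its own 120 degree sector), `"shared_sweep"` (all players follow one
#'   shared waypoint route), `"random_walk"`, or `"corral_nearest"`.
#' @param sense_radius Visual range in meters.
#' @param global_info Logical; HUD-style global information.
#' @param scan_amplitude Amplitude of the sinusoidal head scan, radians.
#' @param scan_period Period of the head scan, seconds.
#' @param heading_noise_sd SD of Gaussian noise added to head orientation,
#'   radians.
#' @param move_noise_sd SD of Gaussian jitter applied to the commanded
#'   movement direction at every control tick, radians. The default `NA`
#'   scales the jitter with informational uncertainty — smooth, prospective
#'   steering (0.04) with global information and clear sight, large reactive
#'   corrections (up to about 0.3) under fog without a HUD — emulating the
#'   loss of prospective movement control the task manipulations induce in
#'   human players.
#' @param control_hz Rate at which the policy recomputes its control,
#'   Hz (held constant between decisions; physics still runs at
#'   `physics_hz`).
#' @return An object of class `herd_policy_config`.
#' @export
policy_config <- function(strategy = c("partitioned_sweep", "shared_sweep",
                                       "random_walk", "corral_nearest"),
                          sense_radius = 150,
                          global_info = TRUE,
                          scan_amplitude = 0.6,
                          scan_period = 2,
                          heading_noise_sd = 0.05,
                          move_noise_sd = NA,
                          control_hz = 10) {
  strategy <- match.arg(strategy)
  if (!is.numeric(sense_radius) || sense_radius <= 0) {
    stop("policy_config: `sense_radius` must be > 0", call. = FALSE)
  }
  if (!is.numeric(scan_period) || scan_period <= 0) {
    stop("policy_config: `scan_period` must be > 0", call. = FALSE)
  }
  if (scan_amplitude < 0 || heading_noise_sd < 0) {
    stop("policy_config: scan parameters must be >= 0", call. = FALSE)
  }
  if (is.na(move_noise_sd)) {
    # reactive-steering jitter grows as task information shrinks
    move_noise_sd <- 0.04 +
      (if (isTRUE(global_info)) 0 else 0.12) +
      (if (sense_radius < 50) 0.18 else 0)
  }
  if (move_noise_sd < 0) {
    stop("policy_config: `move_noise_sd` must be >= 0", call. = FALSE)
  }
  cfg <- list(
    strategy = strategy,
    sense_radius = sense_radius,
    global_info = isTRUE(global_info),
    scan_amplitude = scan_amplitude,
    scan_period = scan_period,
    heading_noise_sd = heading_noise_sd,
    move_noise_sd = move_noise_sd,
    control_hz = control_hz
  )
  class(cfg) <- "herd_policy_config"
  cfg
}
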