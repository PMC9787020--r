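# Scripted player policies. These are explicit stand-ins for human teams:
# they search (by strategy), corral visible TAs by approaching from the far
# side relative to the containment area and pushing inward, and shepherd the
# contained flock once targets accumulate. No claim of behavioral
# equivalence to human players is made; their role is to produce trial logs
# with the same schema and qualitative condition effects as the human study.

#' Build a player's observation of the world
#'
#' With `global_info = TRUE` (HUD emulation) the observation carries the
#' positions, headings, and statuses of all avatars and TAs. Otherwise
#' (compass emulation) only entities within `sense_radius` of the player are
#' included. The containment-area location is always available (it was
#' provided as a landmark in both information conditions), as is the count
#' of currently contained TAs (standing in for the verbal count a guarding
#' teammate communicates).
#'
#' @param state World-state list.
#' @param policy A [policy_config()].
#' @param player_index Player number (1-3).
#' @param config A [world_config()].
#' @return A named list; `tas` holds the visible TA indices, positions,
#'   velocities, and statuses.
#' @export
policy_observe <- function(state, policy, player_index, config) {
  self <- state$av_pos[player_index, ]
  ctr <- config$containment_center
  n <- nrow(state$ta_pos)
  if (policy$global_info) {
    vis <- rep(TRUE, n)
  } else {
    dx <- state$ta_pos[, 1L] - self[1L]
    dy <- state$ta_pos[, 2L] - self[2L]
    vis <- dx * dx + dy * dy <= policy$sense_radius^2
  }
  others <- setdiff(1:3, player_index)
  contained <- state$ta_status >= TA_STATUS[["contained"]]
  list(
    t = state$t,
    player_index = player_index,
    self_pos = self,
    self_heading = state$av_head[player_index],
    containment = list(
      center = ctr,
      radius = config$containment_diameter / 2,
      bearing = atan2(ctr[2L] - self[2L], ctr[1L] - self[1L]),
      distance = sqrt(sum((ctr - self)^2))
    ),
    n_targets = n,
    n_contained = sum(contained),
    tas = list(
      idx = which(vis),
      pos = state$ta_pos[vis, , drop = FALSE],
      vel = state$ta_vel[vis, , drop = FALSE],
      status = state$ta_status[vis]
    ),
    players = if (policy$global_info) {
      list(idx = others,
           pos = state$av_pos[others, , drop = FALSE],
           heading = state$av_head[others])
    } else {
      NULL
    }
  )
}

#' Initialize mutable policy state for one player
#'
#' @param player_index Player number (1-3).
#' @param policy A [policy_config()].
#' @param wp_stream RNG substream for waypoint draws (shared across players
#'   for the `shared_sweep` strategy).
#' @param noise_stream RNG substream for head-scan noise.
#' @return An environment holding waypoint, target, and heading memory.
#' @export
policy_init <- function(player_index, policy, wp_stream, noise_stream) {
  e <- new.env(parent = emptyenv())
  e$player_index <- player_index
  e$sector <- (player_index - 1) * 2 * pi / 3 # center angle of own 120 deg sector
  e$phase <- (player_index - 1) * 2 * pi / 3  # head-scan phase offset
  e$waypoint <- NULL
  e$waypoint_t <- -Inf
  e$target <- NA_integer_
  e$last_heading <- 0
  e$wp_stream <- wp_stream
  e$noise_stream <- noise_stream
  e
}

# smallest signed difference a - b wrapped to (-pi, pi]
angle_diff <- function(a, b) wrap_angle(a - b)

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) c(1, 0) else v / n
}

# Movement direction from `self` to `target`, detouring around a keep-out
# circle at `ctr` so players do not barge through the containment area and
# scatter contained TAs with their repulsion field.
nav_dir <- function(self, target, ctr, keepout) {
  v <- target - self
  L <- sqrt(sum(v^2))
  if (L < 1e-9) return(NA_real_)
  w <- ctr - self
  proj <- sum(w * v) / L
  d_self <- sqrt(sum(w^2))
  if (proj > 0 && proj < L && d_self > keepout &&
      sum((target - ctr)^2) > keepout^2) {
    d_perp2 <- sum(w^2) - proj^2
    if (d_perp2 < keepout^2) {
      r <- self - ctr
      tang <- c(-r[2L], r[1L]) / d_self
      if (sum(tang * v) < 0) tang <- -tang
      return(atan2(tang[2L], tang[1L]))
    }
  }
  atan2(v[2L], v[1L])
}

# One herding maneuver against a single TA at `tp` (velocity `tv`): push it
# radially toward the containment center from a tracking point just outside
# it, orbit to the far side first when approaching from the wrong side, and
# release (back off) once the TA will coast to within `release_r` of the
# center under linear drag `gamma`.
herd_maneuver <- function(self, tp, tv, ctr, gamma, push_dist, standoff,
                          release_r, orbit_r, disc_r) {
  u <- unit_vec(tp - ctr)
  dc <- sqrt(sum((tp - ctr)^2))
  vr <- sum(tv * u)
  predicted_stop <- dc + vr / max(gamma, 1e-6)
  if (vr < 0 && predicted_stop < release_r) {
    # the TA is on course; retreat so the repulsion field stops stirring
    d_self <- sqrt(sum((self - ctr)^2))
    dir <- if (d_self < disc_r + 8) {
      atan2(self[2L] - ctr[2L], self[1L] - ctr[1L])
    } else {
      NA_real_
    }
    return(list(move_dir = dir, target = tp + standoff * u, slow = TRUE))
  }
  rel <- self - tp
  d <- sqrt(sum(rel^2))
  cosang <- if (d > 0) sum(rel * u) / d else -1
  if (d < orbit_r + 4 && cosang > 0.5) {
    # roughly behind the TA: push by tracking a point just outside it
    target <- tp + push_dist * u
    list(move_dir = atan2(target[2L] - self[2L], target[1L] - self[1L]),
         target = target, slow = FALSE)
  } else if (d < orbit_r + 2) {
    # close but on the wrong side: swing around the TA toward its far side
    # instead of shoving it away from the containment area
    tang <- c(-rel[2L], rel[1L]) / max(d, 1e-9)
    if (sum(tang * u) < 0) tang <- -tang
    radial <- rel / max(d, 1e-9) * (orbit_r - d) / 4
    dirv <- unit_vec(tang + radial)
    list(move_dir = atan2(dirv[2L], dirv[1L]),
         target = tp + orbit_r * unit_vec(rel), slow = FALSE)
  } else {
    # far away: approach the standoff point, detouring around both the
    # containment area and the TA itself
    target <- tp + standoff * u
    dir <- nav_dir(self, target, ctr, disc_r + 4)
    direct <- atan2(target[2L] - self[2L], target[1L] - self[1L])
    if (!is.na(dir) && isTRUE(all.equal(dir, direct))) {
      dir <- nav_dir(self, target, tp, 5)
    }
    list(move_dir = dir, target = target, slow = FALSE)
  }
}

# Pick the TA (index into obs$tas rows) this player should corral.
# partitioned_sweep prefers TAs in the player's own sector. With global
# information all players compute the same greedy player-TA assignment from
# the shared distance matrix, so they spread over distinct targets without
# explicit communication; with local sensing the player keeps its previous
# target while visible, else takes the nearest.
choose_corral_target <- function(obs, pstate, policy, cand, ctr) {
  ta <- obs$tas
  self <- obs$self_pos
  if (policy$strategy == "partitioned_sweep") {
    bear <- atan2(ta$pos[cand, 2L] - ctr[2L], ta$pos[cand, 1L] - ctr[1L])
    own <- abs(angle_diff(bear, pstate$sector)) <= pi / 3
    if (any(own)) cand <- cand[own]
  }
  if (!is.null(obs$players) && length(cand) > 1L &&
      policy$strategy != "partitioned_sweep") {
    pos <- matrix(NA_real_, 3L, 2L)
    pos[obs$player_index, ] <- self
    pos[obs$players$idx, ] <- obs$players$pos
    d <- outer(seq_len(3L), seq_along(cand), function(i, j) {
      sqrt((pos[i, 1L] - ta$pos[cand[j], 1L])^2 +
             (pos[i, 2L] - ta$pos[cand[j], 2L])^2)
    })
    players_left <- seq_len(3L)
    cand_left <- seq_along(cand)
    while (length(players_left) && length(cand_left)) {
      sub <- d[players_left, cand_left, drop = FALSE]
      w <- arrayInd(which.min(sub), dim(sub))
      p <- players_left[w[1L]]
      j <- cand_left[w[2L]]
      if (p == obs$player_index) return(cand[j])
      players_left <- setdiff(players_left, p)
      cand_left <- setdiff(cand_left, j)
    }
    # more players than candidates: unassigned players fall through
  }
  keep <- if (!is.na(pstate$target)) which(ta$idx[cand] == pstate$target) else integer()
  if (length(keep) == 1L) return(cand[keep])
  d2 <- (ta$pos[cand, 1L] - self[1L])^2 + (ta$pos[cand, 2L] - self[2L])^2
  cand[which.min(d2)]
}

draw_waypoint <- function(pstate, policy, config, self) {
  ctr <- config$containment_center
  r_max <- config$ta_spawn_radius * 1.05
  stream_do(pstate$wp_stream, function() {
    u <- runif(2L)
    if (policy$global_info || policy$strategy == "shared_sweep") {
      # shared_sweep always walks a communal absolute route: the whole
      # team consumes the identical waypoint sequence, searching together
      # with global awareness players plan long legs anywhere in the field
      # (restricted to the own sector under partitioned_sweep)
      r <- r_max * sqrt(u[1L])
      a <- switch(policy$strategy,
        partitioned_sweep = pstate$sector + (u[2L] - 0.5) * 2 * pi / 3,
        # shared and random strategies draw from the full circle; shared_sweep
        # players consume an identical stream, so they visit identical
        # waypoints
        (u[2L] - 0.5) * 2 * pi
      )
      ctr + r * c(cos(a), sin(a))
    } else {
      # without global information, search is reactive: short local legs
      # scaled by how far the player can see, redirected far more often
      leg <- 15 + (min(policy$sense_radius, r_max) + 25) * u[1L]
      a <- switch(policy$strategy,
        partitioned_sweep = pstate$sector + (u[2L] - 0.5) * 2 * pi / 3,
        (u[2L] - 0.5) * 2 * pi
      )
      wp <- self + leg * c(cos(a), sin(a))
      # reflect legs that would leave the search field back inward
      if (sqrt(sum((wp - ctr)^2)) > r_max) {
        wp <- self + leg * (ctr - self) / max(sqrt(sum((ctr - self)^2)), 1)
      }
      wp
    }
  })
}

#' Compute one player's control from its observation
#'
#' Behavior has four phases, in priority order. (1) *Flock shepherding*:
#' once every target is either contained or hovering near the containment
#' area, the players split the plane into three sectors and each escorts the
#' outermost TA of its sector deep toward the center, retreating to a post
#' outside the repulsion radius in between so the flock is not stirred.
#' (2) *Corralling*: a visible uncontained TA is approached from its far
#' side relative to the containment area and pushed inward; with global
#' information players spread over distinct targets via a shared greedy
#' assignment. (3) *Guarding*: once targets accumulate in the containment
#' area, one, then two, players peel off to escort boundary-drifting TAs
#' back toward the center. (4) *Search*: waypoint selection by strategy —
#' `partitioned_sweep` draws waypoints in the player's own 120 degree
#' sector, `shared_sweep` consumes a waypoint stream shared by the whole
#' team, `random_walk` and `corral_nearest` roam the whole spawn disc. Head
#' orientation is the movement heading plus a sinusoidal scan
#' (`scan_amplitude`, `scan_period`) plus Gaussian noise
#' (`heading_noise_sd`).
#'
#' @param obs Observation from [policy_observe()].
#' @param pstate Policy state from [policy_init()].
#' @param policy A [policy_config()].
#' @param config A [world_config()].
#' @return List with `move_dir` (radians, `NA` = stay), `slow`, `head`, and
#'   the diagnostic `target` point (commanded position, or `NULL`).
#' @export
policy_act <- function(obs, pstate, policy, config) {
  ctr <- obs$containment$center
  disc_r <- obs$containment$radius
  self <- obs$self_pos
  gamma <- config$drag_coefficient
  post_r <- disc_r + 7.5

  ta <- obs$tas
  uncontained <- ta$status < TA_STATUS[["contained"]]
  n_vis <- length(ta$idx)
  dc <- if (n_vis) {
    sqrt((ta$pos[, 1L] - ctr[1L])^2 + (ta$pos[, 2L] - ctr[2L])^2)
  } else {
    numeric(0)
  }

  target_pt <- NULL
  move_dir <- NA_real_
  slow <- FALSE

  endgame <- obs$n_contained == obs$n_targets
  # guard duty scales with the contained flock: one guard once anything is
  # contained, two once half the targets are in, all three at the endgame
  n_guards <- if (endgame) {
    3L
  } else if (obs$n_contained == 0L) {
    0L
  } else if (obs$n_contained >= obs$n_targets - 2L) {
    2L
  } else {
    1L
  }
  guard_role <- pstate$player_index <= n_guards

  # every target accounted for and near the containment area?
  flock <- n_vis > 0L &&
    obs$n_contained + sum(uncontained) >= obs$n_targets &&
    max(dc) < 16

  goto_post <- function() {
    post <- ctr + post_r * c(cos(pstate$sector), sin(pstate$sector))
    d_post <- sqrt(sum((self - post)^2))
    if (d_post > 0.3) {
      list(move_dir = nav_dir(self, post, ctr, disc_r + 4), target = post,
           slow = d_post < 6)
    } else {
      list(move_dir = NA_real_, target = post, slow = FALSE)
    }
  }

  if (flock) {
    pstate$target <- NA_integer_
    bear <- atan2(ta$pos[, 2L] - ctr[2L], ta$pos[, 1L] - ctr[1L])
    mine <- which(abs(angle_diff(bear, pstate$sector)) <= pi / 3 & dc > 3.0)
    mv <- if (length(mine)) {
      worst <- mine[which.max(dc[mine])]
      herd_maneuver(self, ta$pos[worst, ], ta$vel[worst, ], ctr, gamma,
                    push_dist = 2.3, standoff = 3.5, release_r = 1.2,
                    orbit_r = 5, disc_r = disc_r)
    } else {
      goto_post()
    }
    move_dir <- mv$move_dir
    target_pt <- mv$target
    slow <- mv$slow
  } else {
    cand <- which(uncontained)
    if (guard_role && length(cand)) {
      # guards only leave their post for TAs near the containment area
      cand <- cand[dc[cand] < 35]
    } else if (n_guards > 0L && length(cand) &&
               any(dc[cand] >= 35)) {
      # fetchers leave near-containment escapees to the guards and go for
      # the targets still out in the field
      cand <- cand[dc[cand] >= 35]
    }
    if (length(cand)) {
      pick <- choose_corral_target(obs, pstate, policy, cand, ctr)
      pstate$target <- ta$idx[pick]
      mv <- herd_maneuver(self, ta$pos[pick, ], ta$vel[pick, ], ctr, gamma,
                          push_dist = 2.5, standoff = 6,
                          release_r = disc_r * 0.5, orbit_r = 9,
                          disc_r = disc_r)
      move_dir <- mv$move_dir
      target_pt <- mv$target
      slow <- mv$slow
    } else if (guard_role) {
      pstate$target <- NA_integer_
      # escort contained TAs drifting toward the containment boundary back
      # inward; multiple guards spread via a shared greedy assignment
      pick <- NA_integer_
      if (n_vis) {
        risky <- which(!uncontained & dc > disc_r * 0.7)
        if (length(risky)) {
          guards <- seq_len(n_guards)
          if (!is.null(obs$players) && n_guards > 1L && length(risky) > 1L) {
            pos <- matrix(NA_real_, 3L, 2L)
            pos[obs$player_index, ] <- self
            pos[obs$players$idx, ] <- obs$players$pos
            d <- outer(guards, seq_along(risky), function(i, j) {
              sqrt((pos[i, 1L] - ta$pos[risky[j], 1L])^2 +
                     (pos[i, 2L] - ta$pos[risky[j], 2L])^2)
            })
            g_left <- guards
            r_left <- seq_along(risky)
            while (length(g_left) && length(r_left)) {
              sub <- d[g_left, r_left, drop = FALSE]
              w <- arrayInd(which.min(sub), dim(sub))
              if (g_left[w[1L]] == obs$player_index) {
                pick <- risky[r_left[w[2L]]]
                break
              }
              g_left <- g_left[-w[1L]]
              r_left <- r_left[-w[2L]]
            }
          } else {
            d2 <- (ta$pos[risky, 1L] - self[1L])^2 +
              (ta$pos[risky, 2L] - self[2L])^2
            pick <- risky[which.min(d2)]
          }
        }
      }
      if (!is.na(pick)) {
        mv <- herd_maneuver(self, ta$pos[pick, ], ta$vel[pick, ], ctr, gamma,
                            push_dist = 2.5, standoff = 3.5, release_r = 1.2,
                            orbit_r = 5, disc_r = disc_r)
      } else {
        mv <- goto_post()
      }
      move_dir <- mv$move_dir
      target_pt <- mv$target
      slow <- mv$slow
    } else {
      pstate$target <- NA_integer_
      stale <- obs$t - pstate$waypoint_t > 45
      reached <- !is.null(pstate$waypoint) &&
        sqrt(sum((self - pstate$waypoint)^2)) < 5
      if (is.null(pstate$waypoint) || reached || stale) {
        pstate$waypoint <- draw_waypoint(pstate, policy, config, self)
        pstate$waypoint_t <- obs$t
      }
      target_pt <- pstate$waypoint
      move_dir <- nav_dir(self, target_pt, ctr, disc_r + 4)
    }
  }
  if (!is.null(target_pt) && !is.na(move_dir) &&
      sqrt(sum((self - target_pt)^2)) < 0.2) {
    move_dir <- NA_real_
  }

  if (!is.na(move_dir) && policy$move_noise_sd > 0) {
    move_dir <- wrap_angle(move_dir +
      stream_do(pstate$noise_stream, rnorm, 1L, 0, policy$move_noise_sd))
  }

  base_heading <- if (is.na(move_dir)) pstate$last_heading else move_dir
  pstate$last_heading <- base_heading
  noise <- if (policy$heading_noise_sd > 0) {
    stream_do(pstate$noise_stream, rnorm, 1L, 0, policy$heading_noise_sd)
  } else {
    0
  }
  head <- base_heading +
    policy$scan_amplitude * sin(2 * pi * obs$t / policy$scan_period + pstate$phase) +
    noise

  list(move_dir = move_dir, slow = slow, head = wrap_angle(head),
       target = target_pt)
}
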