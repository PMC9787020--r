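#' Sample the 1 Hz Brownian driving force of the target agents
#'
#' Each TA is driven by a random planar force with magnitude uniform on
#' `[0, brownian_force_max]` newtons and direction uniform on the circle,
#' redrawn at `brownian_rate` (1 Hz by default) and held constant in between.
#'
#' @param n Number of force vectors to draw (one per TA).
#' @param force_max Upper magnitude bound in newtons.
#' @return An `n x 2` matrix of force components in newtons.
#' @export
sample_brownian_force <- function(n, force_max = 60) {
  mag <- runif(n, 0, force_max)
  ang <- runif(n, 0, 2 * pi)
  cbind(mag * cos(ang), mag * sin(ang))
}

#' Repulsive force exerted on target agents by a nearby avatar
#'
#' An avatar within `radius` (10 m) of a TA pushes it directly away with a
#' magnitude inversely proportional to the avatar-TA distance,
#' `min(force_max, c / d)` with `c = force_max * 1 m`, so the 450 N cap
#' engages at distances of 1 m and below. Beyond `radius` the force is zero.
#' At exactly zero distance the direction is undefined; the force is returned
#' along `+x` at the cap (a deterministic fallback).
#'
#' @param ta_pos TA positions, an `n x 2` matrix (meters).
#' @param avatar_pos A single avatar position `c(x, y)` (meters).
#' @param radius Interaction radius, m.
#' @param force_max Force cap, N.
#' @return An `n x 2` matrix of force components in newtons.
#' @export
repulsion_force <- function(ta_pos, avatar_pos, radius = 10, force_max = 450) {
  ta_pos <- matrix(ta_pos, ncol = 2L)
  dx <- ta_pos[, 1L] - avatar_pos[1L]
  dy <- ta_pos[, 2L] - avatar_pos[2L]
  d <- sqrt(dx * dx + dy * dy)
  mag <- ifelse(d <= radius, pmin(force_max, force_max / d), 0)
  zero <- d == 0
  if (any(zero)) {
    # distance exactly zero: cap magnitude, push along +x
    dx[zero] <- 1
    dy[zero] <- 0
    d[zero] <- 1
    mag[zero] <- force_max
  }
  cbind(mag * dx / d, mag * dy / d)
}
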