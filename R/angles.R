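# Construction of the two 5 Hz movement-fluctuation series analyzed by DFA:
# the displacement angle of the position track and the wrap-aware change in
# head orientation, both computed after decimation to 5 Hz and removal of
# the first second of the trial.

#' Downsample a track by decimation and trim the initial transient
#'
#' Keeps every `(from_hz / to_hz)`-th sample starting from the first, then
#' removes the first `to_hz` kept samples (one second) to discard the
#' transient at trial start. Decimation is used deliberately — no filtering
#' or interpolation — so the retained samples are actual logged states.
#'
#' @param track Numeric vector or matrix (rows = samples).
#' @param from_hz Original sample rate; must be a multiple of `to_hz`.
#' @param to_hz Target rate (default 5).
#' @param trim_seconds Seconds removed from the start after decimation.
#' @return The decimated, trimmed track (same type as input).
#' @export
downsample_track <- function(track, from_hz, to_hz = 5, trim_seconds = 1) {
  if (from_hz %% to_hz != 0) {
    stop("downsample_track: `from_hz` (", from_hz,
         ") is not a multiple of `to_hz` (", to_hz,
         "); resampling by interpolation is not offered", call. = FALSE)
  }
  by <- as.integer(from_hz / to_hz)
  n <- if (is.matrix(track)) nrow(track) else length(track)
  keep <- seq.int(1L, n, by = by)
  drop <- seq_len(min(length(keep), as.integer(round(to_hz * trim_seconds))))
  keep <- keep[-drop]
  if (is.matrix(track)) track[keep, , drop = FALSE] else track[keep]
}

new_angle_series <- function(values, kind, sample_rate, source_player = NA) {
  structure(list(
    values = as.numeric(values),
    kind = kind,
    sample_rate = sample_rate,
    source_player = source_player,
    n = length(values)
  ), class = "herd_angle_series")
}

#' @export
print.herd_angle_series <- function(x, ...) {
  cat("<herd_angle_series> kind:", x$kind, "| n:", x$n,
      "| rate:", x$sample_rate, "Hz\n")
  invisible(x)
}

#' Displacement-angle fluctuation series
#'
#' The angle of the position displacement vector between adjacent
#' timepoints: `value_t = atan2(y_{t+1} - y_t, x_{t+1} - x_t)`, in
#' `(-pi, pi]`, length `nrow(positions) - 1`. The angle is undefined for a
#' stationary frame; by default the last defined angle is held (0 before any
#' motion), which avoids injecting artificial jumps into the series —
#' `zero_policy = "zero"` emits 0 instead. Angles are reported raw (not
#' unwrapped).
#'
#' @param positions Two-column matrix of positions at the analysis rate
#'   (already decimated and trimmed; see [downsample_track()]).
#' @param sample_rate Sample rate of `positions`, Hz.
#' @param zero_policy Handling of zero-displacement frames: `"hold"`
#'   (default) or `"zero"`.
#' @param source_player Optional identifier stored with the series.
#' @return A `herd_angle_series`.
#' @export
displacement_angle_series <- function(positions, sample_rate = 5,
                                      zero_policy = c("hold", "zero"),
                                      source_player = NA) {
  zero_policy <- match.arg(zero_policy)
  positions <- as.matrix(positions)
  if (nrow(positions) < 2L) {
    stop("displacement_angle_series: need at least 2 positions",
         call. = FALSE)
  }
  dx <- diff(positions[, 1L])
  dy <- diff(positions[, 2L])
  ang <- atan2(dy, dx)
  still <- dx == 0 & dy == 0
  if (any(still)) {
    if (zero_policy == "zero") {
      ang[still] <- 0
    } else {
      # hold the last defined angle forward; 0 before any motion
      last <- 0
      for (i in seq_along(ang)) {
        if (still[i]) ang[i] <- last else last <- ang[i]
      }
    }
  }
  new_angle_series(ang, "displacement_angle", sample_rate, source_player)
}

#' Head-orientation-change fluctuation series
#'
#' The wrap-aware change in head-orientation angle between adjacent
#' timepoints: the smallest signed difference `heading_{t+1} - heading_t`
#' in `(-pi, pi]`, length `length(headings) - 1`.
#'
#' @param headings Numeric vector of head orientations (radians) at the
#'   analysis rate.
#' @inheritParams displacement_angle_series
#' @return A `herd_angle_series`.
#' @export
head_orientation_change_series <- function(headings, sample_rate = 5,
                                           source_player = NA) {
  if (length(headings) < 2L) {
    stop("head_orientation_change_series: need at least 2 headings",
         call. = FALSE)
  }
  d <- wrap_angle(diff(headings))
  new_angle_series(d, "head_orientation_change", sample_rate, source_player)
}

#' Build a player's fluctuation series from a trial log
#'
#' Applies the full preparation chain — decimate the 90 Hz track to 5 Hz,
#' delete the first second, then difference — for either series kind.
#'
#' @param log A `herd_trial_log`.
#' @param player Player index (1-3).
#' @param kind `"displacement_angle"` or `"head_orientation_change"`.
#' @param to_hz Analysis rate, Hz.
#' @param ... Passed to the series constructor.
#' @return A `herd_angle_series`.
#' @export
prepare_angle_series <- function(log, player,
                                 kind = c("displacement_angle",
                                          "head_orientation_change"),
                                 to_hz = 5, ...) {
  kind <- match.arg(kind)
  stopifnot(inherits(log, "herd_trial_log"), player %in% 1:3)
  if (kind == "displacement_angle") {
    pos <- cbind(log$player_x[, player], log$player_y[, player])
    pos <- downsample_track(pos, log$sample_rate, to_hz)
    displacement_angle_series(pos, to_hz, source_player = player, ...)
  } else {
    h <- downsample_track(log$player_head[, player], log$sample_rate, to_hz)
    head_orientation_change_series(h, to_hz, source_player = player, ...)
  }
}
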