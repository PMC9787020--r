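#' Detrended fluctuation analysis configuration
#'
#' The window schedule starts at `min_window` samples (five points = one
#' second at the 5 Hz analysis rate) and grows geometrically by `growth`
#' (1.2) until the largest window below `max_window_fraction` (10%) of the
#' series length; windows are placed with `overlap_fraction` (50%) overlap
#' and detrended with a polynomial of degree `detrend_order` (linear).
#'
#' @param min_window Smallest window, samples.
#' @param growth Multiplicative window growth factor (> 1).
#' @param overlap_fraction Fractional overlap of consecutive windows,
#'   in `[0, 1)`.
#' @param max_window_fraction Windows must stay strictly below this fraction
#'   of the series length.
#' @param detrend_order Degree of the detrending polynomial.
#' @param statistic Per-window-size summary of the per-window residual SDs:
#'   `"mean_sd"` (arithmetic mean of SDs, the default) or `"rms"`
#'   (root-mean-square, the more common DFA convention).
#' @return A `herd_dfa_config` list.
#' @export
dfa_config <- function(min_window = 5, growth = 1.2, overlap_fraction = 0.5,
                       max_window_fraction = 0.10, detrend_order = 1,
                       statistic = c("mean_sd", "rms")) {
  statistic <- match.arg(statistic)
  if (growth <= 1) stop("dfa_config: `growth` must be > 1", call. = FALSE)
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("dfa_config: `overlap_fraction` must be in [0, 1)", call. = FALSE)
  }
  if (min_window <= detrend_order + 1) {
    stop("dfa_config: `min_window` must exceed `detrend_order` + 1",
         call. = FALSE)
  }
  if (max_window_fraction <= 0 || max_window_fraction > 1) {
    stop("dfa_config: `max_window_fraction` must be in (0, 1]", call. = FALSE)
  }
  structure(list(min_window = as.integer(min_window), growth = growth,
                 overlap_fraction = overlap_fraction,
                 max_window_fraction = max_window_fraction,
                 detrend_order = as.integer(detrend_order),
                 statistic = statistic),
            class = "herd_dfa_config")
}

#' Integrated (cumulative-sum) profile of a series
#'
#' Subtracts the series mean and takes the cumulative sum; the final profile
#' value is zero up to rounding.
#'
#' @param x Numeric series.
#' @return Numeric profile of the same length.
#' @export
dfa_profile <- function(x) {
  if (length(x) < 2L || anyNA(x) || any(!is.finite(x))) {
    stop("dfa_profile: need >= 2 finite values", call. = FALSE)
  }
  cumsum(x - mean(x))
}

#' Geometric window schedule
#'
#' Window sizes `min_window * growth^k`, rounded to the nearest integer and
#' deduplicated, keeping every size strictly below
#' `n * max_window_fraction`. At least two distinct sizes are required to
#' fit a slope.
#'
#' @param n Series length.
#' @param config A [dfa_config()].
#' @return Integer vector of window sizes, strictly increasing.
#' @export
dfa_window_schedule <- function(n, config = dfa_config()) {
  limit <- n * config$max_window_fraction
  sizes <- integer(0)
  w <- as.numeric(config$min_window)
  while (round(w) < limit) {
    sizes <- c(sizes, as.integer(round(w)))
    w <- w * config$growth
  }
  sizes <- unique(sizes)
  if (length(sizes) < 2L) {
    stop("insufficient length for DFA: n = ", n, " admits ", length(sizes),
         " window size(s) below ", format(limit), call. = FALSE)
  }
  sizes
}

#' Mean detrended fluctuation at one window size
#'
#' Windows of length `window` are placed from the start of the profile with
#' the configured overlap (step `max(1, floor(window * (1 -
#' overlap_fraction)))`); a trailing partial window is discarded. Each
#' window is detrended by a least-squares polynomial of degree
#' `detrend_order` and the SD of the residuals (root mean square; the
#' residuals of a fitted polynomial with intercept have zero mean) is
#' summarized across windows by the configured statistic.
#'
#' @param profile Profile from [dfa_profile()].
#' @param window Window length, samples.
#' @param config A [dfa_config()].
#' @return The fluctuation value (a scalar).
#' @export
dfa_fluctuation <- function(profile, window, config = dfa_config()) {
  n <- length(profile)
  window <- as.integer(window)
  if (window > n) {
    stop("dfa_fluctuation: window exceeds profile length", call. = FALSE)
  }
  if (window <= config$detrend_order + 1L) {
    stop("dfa_fluctuation: window too small for detrend order", call. = FALSE)
  }
  step <- max(1L, as.integer(floor(window * (1 - config$overlap_fraction))))
  starts <- seq.int(1L, n - window + 1L, by = step)
  idx <- outer(seq_len(window) - 1L, starts, `+`)
  Y <- matrix(profile[idx], nrow = window)
  t_in <- seq_len(window)
  X <- outer(t_in, 0:config$detrend_order, `^`)
  res <- qr.resid(qr(X), Y)
  sds <- sqrt(colMeans(res^2))
  switch(config$statistic,
         mean_sd = mean(sds),
         rms = sqrt(mean(sds^2)))
}

#' DFA scaling exponent of a series
#'
#' Full procedure: mean-subtracted cumulative sum, detrended fluctuation at
#' each window of the geometric schedule, and the OLS slope of
#' `log10(fluctuation)` against `log10(window)` — the scaling exponent
#' alpha. Values near 0.5 indicate uncorrelated (white) fluctuations,
#' below 0.5 antipersistence, near 1.0 pink-noise (fractal) structure, and
#' near 1.5 Brownian (integrated) persistence.
#'
#' @param x Numeric series or `herd_angle_series`.
#' @param config A [dfa_config()].
#' @param min_length Guard: shortest series accepted.
#' @return A `herd_dfa` object: `alpha`, `window_sizes`, `fluctuations`,
#'   `fit_r2`, `n`, `config`.
#' @export
dfa_alpha <- function(x, config = dfa_config(), min_length = 50) {
  if (inherits(x, "herd_angle_series")) x <- x$values
  x <- as.numeric(x)
  n <- length(x)
  if (n < min_length) {
    stop("insufficient length for DFA: n = ", n, " < ", min_length,
         call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("dfa_alpha: series contains non-finite values", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("dfa_alpha: series is constant; fluctuation is zero at every scale",
         call. = FALSE)
  }
  prof <- dfa_profile(x)
  sizes <- dfa_window_schedule(n, config)
  fl <- vapply(sizes, function(w) dfa_fluctuation(prof, w, config),
               numeric(1L))
  if (any(fl <= 0)) {
    stop("dfa_alpha: zero fluctuation at some window size", call. = FALSE)
  }
  fit <- lm(log10(fl) ~ log10(sizes))
  structure(list(
    alpha = unname(coef(fit)[2L]),
    window_sizes = sizes,
    fluctuations = fl,
    fit_r2 = summary(fit)$r.squared,
    n = n,
    config = config
  ), class = "herd_dfa")
}

#' @export
print.herd_dfa <- function(x, ...) {
  cat("<herd_dfa> alpha:", format(x$alpha, digits = 4),
      "| windows:", length(x$window_sizes),
      sprintf("(%d-%d)", min(x$window_sizes), max(x$window_sizes)),
      "| n:", x$n, "| fit R2:", format(x$fit_r2, digits = 3), "\n")
  invisible(x)
}

#' Calibrated noise generators
#'
#' Reference processes with known scaling exponents, used to validate the
#' DFA implementation: `white` (iid standard Gaussian, alpha 0.5), `brown`
#' (cumulative sum of white, alpha 1.5), `pink` (spectral synthesis — the
#' Fourier amplitudes of a white series are scaled by `f^(-1/2)` and
#' inverted, giving a 1/f power spectrum and alpha 1.0; standardized to unit
#' variance), and `antipersistent` (first difference of white, alpha below
#' 0.5).
#'
#' @param kind One of `"white"`, `"pink"`, `"brown"`, `"antipersistent"`.
#' @param n Series length.
#' @param seed Optional seed; when given, the draw is deterministic and the
#'   caller's RNG state is left untouched.
#' @return Numeric series of length `n`.
#' @export
generate_noise <- function(kind = c("white", "pink", "brown", "antipersistent"),
                           n, seed = NULL) {
  kind <- match.arg(kind)
  if (n < 2L) stop("generate_noise: n must be >= 2", call. = FALSE)
  draw <- function() {
    switch(kind,
      white = rnorm(n),
      brown = cumsum(rnorm(n)),
      antipersistent = diff(rnorm(n + 1L)),
      pink = {
        w <- rnorm(n)
        spec <- fft(w)
        k <- seq_len(n) - 1L
        f <- pmin(k, n - k) # symmetric frequency index; DC removed below
        scale <- c(0, f[-1L]^(-0.5))
        x <- Re(fft(spec * scale, inverse = TRUE)) / n
        x / sd(x)
      }
    )
  }
  if (is.null(seed)) {
    draw()
  } else {
    stream_do(rng_stream(seed), draw)
  }
}
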