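# Independent oracles, deliberately written in a plain style (explicit
# window index lists, lm() fits, ray casting) and kept separate from the
# package's implementation paths.

# Brute-force DFA: explicit loop over window start indices, lm residuals.
oracle_dfa_fluctuation <- function(profile, w, overlap = 0.5) {
  n <- length(profile)
  step <- max(1, floor(w * (1 - overlap)))
  starts <- seq(1, n - w + 1, by = step)
  sds <- numeric(length(starts))
  for (k in seq_along(starts)) {
    seg <- profile[starts[k]:(starts[k] + w - 1)]
    tt <- seq_len(w)
    r <- stats::residuals(stats::lm(seg ~ tt))
    sds[k] <- sqrt(mean(r^2))
  }
  mean(sds)
}

oracle_dfa_alpha <- function(x, min_window = 5, growth = 1.2, frac = 0.1) {
  prof <- cumsum(x - mean(x))
  n <- length(x)
  sizes <- c()
  w <- min_window
  while (round(w) < n * frac) {
    sizes <- c(sizes, round(w))
    w <- w * growth
  }
  sizes <- unique(sizes)
  fl <- vapply(sizes, function(w) oracle_dfa_fluctuation(prof, w),
               numeric(1))
  unname(stats::coef(stats::lm(log10(fl) ~ log10(sizes)))[2])
}

# Even-odd ray-casting point membership for a ring-list region,
# vectorized over query points.
oracle_points_in_region <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (r in rings) {
    xs <- r$x
    ys <- r$y
    nv <- length(xs)
    j <- nv
    for (i in seq_len(nv)) {
      crosses <- ((ys[i] > py) != (ys[j] > py)) &
        (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
      inside <- xor(inside, crosses)
      j <- i
    }
  }
  inside
}

# Monte-Carlo rejection-sampling estimate of the overlap proportion:
# fraction of covered points hit by two or more regions.
oracle_overlap_mc <- function(regions, n_pts = 2e5, seed = 99) {
  all_x <- unlist(lapply(regions, function(rg) unlist(lapply(rg, `[[`, "x"))))
  all_y <- unlist(lapply(regions, function(rg) unlist(lapply(rg, `[[`, "y"))))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  px <- runif(n_pts, min(all_x), max(all_x))
  py <- runif(n_pts, min(all_y), max(all_y))
  cover <- rep(0L, n_pts)
  for (rg in regions) {
    cover <- cover + oracle_points_in_region(px, py, rg)
  }
  sum(cover >= 2) / sum(cover >= 1)
}

# Log-periodogram slope over mid frequencies (for pink-noise validation).
oracle_spectral_slope <- function(x) {
  sp <- stats::spec.pgram(x, taper = 0, detrend = FALSE, plot = FALSE)
  keep <- sp$freq > 0.01 & sp$freq < 0.2
  unname(stats::coef(stats::lm(log10(sp$spec[keep]) ~
                                 log10(sp$freq[keep])))[2])
}

# Hand-assembled log-logistic AFT likelihood, term by term.
oracle_aft_loglik <- function(beta0, beta1, sigma, duration, event, x) {
  total <- 0
  for (i in seq_along(duration)) {
    z <- (log(duration[i]) - beta0 - beta1 * x[i]) / sigma
    if (event[i]) {
      dens <- exp(z) / (sigma * (1 + exp(z))^2)
      total <- total + log(dens)
    } else {
      total <- total + log(1 / (1 + exp(z)))
    }
  }
  total
}
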