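test_that("the integrated profile telescopes to zero", {
  expect_equal(dfa_profile(c(1, -1, 1, -1)), c(1, 0, 1, 0))
  expect_equal(dfa_profile(c(3, 1, 2)), c(1, 0, 0))
  set.seed(4)
  x <- rnorm(500)
  expect_lt(abs(dfa_profile(x)[500]), 1e-9)
})

test_that("the window schedule is geometric, rounded, deduplicated, capped", {
  cfg <- dfa_config()
  ws <- dfa_window_schedule(1495, cfg)
  # independent enumeration of round(5 * 1.2^k) below 10% of n
  expected <- c()
  w <- 5
  while (round(w) < 149.5) {
    expected <- c(expected, round(w))
    w <- w * 1.2
  }
  expect_identical(ws, as.integer(unique(expected)))
  expect_identical(ws[1], 5L)
  expect_true(all(diff(ws) > 0))
  expect_lt(max(ws), 149.5)

  expect_identical(dfa_window_schedule(100, dfa_config(min_window = 4,
                                                       growth = 2)),
                   c(4L, 8L))
  expect_error(dfa_window_schedule(49, cfg), "insufficient length")
})

test_that("fluctuation matches a brute-force oracle and degenerate cases", {
  # perfectly linear profile detrends to zero at every window
  lin <- 0.3 + 1.7 * seq_len(200)
  for (w in c(5, 16, 50)) {
    expect_lt(dfa_fluctuation(lin, w), 1e-10)
  }
  set.seed(12)
  prof <- dfa_profile(rnorm(128))
  # single global window equals the residual SD of one global fit
  expect_equal(dfa_fluctuation(prof, 128),
               oracle_dfa_fluctuation(prof, 128), tolerance = 1e-12)
  expect_equal(dfa_fluctuation(prof, 8),
               oracle_dfa_fluctuation(prof, 8), tolerance = 1e-12)
  expect_error(dfa_fluctuation(prof, 129), "exceeds")
})

test_that("alpha is invariant to scaling and shifts of the series", {
  set.seed(21)
  x <- rnorm(600)
  a <- dfa_alpha(x)$alpha
  expect_equal(dfa_alpha(13.7 * x)$alpha, a, tolerance = 1e-9)
  expect_equal(dfa_alpha(x + 5)$alpha, a, tolerance = 1e-9)
  expect_error(dfa_alpha(rep(1, 600)), "constant")
  expect_error(dfa_alpha(rnorm(20)), "insufficient length")
})

test_that("canonical noises recover their scaling exponents", {
  seeds <- 1:20
  mean_alpha <- function(kind) {
    mean(vapply(seeds, function(s) {
      dfa_alpha(generate_noise(kind, 1495, seed = 3000 + s))$alpha
    }, numeric(1)))
  }
  expect_equal(mean_alpha("white"), 0.5, tolerance = 0.12)
  expect_equal(mean_alpha("pink"), 1.0, tolerance = 0.12)
  expect_equal(mean_alpha("brown"), 1.5, tolerance = 0.12)
  expect_lt(mean_alpha("antipersistent"), 0.5)
})

test_that("noise generators honor their definitions", {
  w <- generate_noise("white", 2000, seed = 5)
  expect_lt(abs(mean(w)), 3 / sqrt(2000))
  expect_identical(generate_noise("brown", 500, seed = 9),
                   cumsum(generate_noise("white", 500, seed = 9)))
  # pink: log-periodogram slope near -1 over mid frequencies
  slopes <- vapply(1:5, function(s) {
    oracle_spectral_slope(generate_noise("pink", 4096, seed = 40 + s))
  }, numeric(1))
  expect_equal(mean(slopes), -1, tolerance = 0.2)
  expect_error(generate_noise("mauve", 100))
})

test_that("alpha increases monotonically with spectral persistence", {
  # spectral-synthesis family f^(-beta/2): beta 0 is white, 1 pink, 2 brown
  synth <- function(beta, n, seed) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    w <- rnorm(n)
    spec <- fft(w)
    k <- seq_len(n) - 1
    f <- pmin(k, n - k)
    scale <- c(0, f[-1]^(-beta / 2))
    Re(fft(spec * scale, inverse = TRUE)) / n
  }
  betas <- c(0, 0.5, 1, 1.5, 2)
  alphas <- sapply(betas, function(b) {
    mean(vapply(1:12, function(s) {
      dfa_alpha(synth(b, 1024, seed = 7000 + s))$alpha
    }, numeric(1)))
  })
  expect_true(all(diff(alphas) > 0))
  pairs <- expand.grid(rep = 1:12, beta = betas)
  pair_alpha <- mapply(function(r, b) {
    dfa_alpha(synth(b, 1024, seed = 7000 + r))$alpha
  }, pairs$rep, pairs$beta)
  expect_gte(cor(pairs$beta, pair_alpha, method = "spearman"), 0.95)
})
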