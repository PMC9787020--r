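test_that("the likelihood matches a hand-summed oracle term by term", {
  duration <- c(42, 300, 117, 300, 8.5)
  event <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  x <- c(0.61, 0.55, 0.72, 0.48, 0.80)
  X <- cbind(1, x)
  for (par in list(c(5, -2, log(0.4)), c(4.2, 0.5, log(1.1)))) {
    expect_equal(
      aft_loglik(par, duration, event, X),
      oracle_aft_loglik(par[1], par[2], exp(par[3]), duration, event, x),
      tolerance = 1e-12
    )
  }
  expect_error(aft_loglik(c(5, -2, 0), c(-1, 10), c(TRUE, TRUE),
                          cbind(1, c(0, 1))), "positive")
})

test_that("the analytic gradient matches central finite differences", {
  d <- simulate_aft(200, intercept = 4.5, beta = c(v = -1.5), sigma = 0.4,
                    cap = 250, seed = 8)
  X <- cbind(1, d$v)
  par <- c(4.2, -1.2, log(0.5))
  g <- herdlab:::aft_gradient(par, d$duration, d$event, X)
  fd <- vapply(1:3, function(i) {
    h <- 1e-6
    e <- replace(rep(0, 3), i, h)
    (aft_loglik(par + e, d$duration, d$event, X) -
        aft_loglik(par - e, d$duration, d$event, X)) / (2 * h)
  }, numeric(1))
  expect_equal(unname(g), fd, tolerance = 1e-5)
})

test_that("without censoring the fitted median matches the sample median", {
  d <- simulate_aft(4000, intercept = 4, sigma = 0.3, cap = Inf, seed = 15)
  f <- fit_aft(d)
  expect_equal(exp(unname(f$coefficients[1])), median(d$duration),
               tolerance = 0.03)
})

test_that("estimates agree with survreg and behave under duplication", {
  d <- simulate_aft(600, intercept = 5, beta = c(dfa = -2), sigma = 0.3,
                    cap = 300, seed = 30)
  f <- fit_aft(d, "dfa")
  sv <- survival::survreg(survival::Surv(duration, event) ~ dfa, data = d,
                          dist = "loglogistic")
  expect_equal(unname(f$coefficients), unname(coef(sv)), tolerance = 1e-5)
  expect_equal(f$scale, sv$scale, tolerance = 1e-5)
  expect_equal(unname(f$se[1:2]),
               unname(sqrt(diag(vcov(sv)))[1:2]), tolerance = 1e-3)
  expect_true(f$converged)

  d2 <- rbind(d, d)
  f2 <- fit_aft(d2, "dfa")
  expect_equal(f2$coefficients, f$coefficients, tolerance = 1e-5)
  expect_equal(unname(f2$se[1:2] / f$se[1:2]), rep(1 / sqrt(2), 2),
               tolerance = 0.01)
})

test_that("degenerate designs are rejected with diagnostics", {
  d <- simulate_aft(50, intercept = 4, sigma = 0.3, cap = 1, seed = 3)
  d$event <- FALSE # everything censored
  expect_error(fit_aft(d), "not identifiable")
  d2 <- simulate_aft(50, intercept = 4, beta = c(a = 1), sigma = 0.3,
                     cap = Inf, seed = 4)
  d2$b <- d2$a # collinear covariate
  expect_error(fit_aft(d2, c("a", "b")), "rank deficient")
  expect_error(fit_aft(d2, "missing_cov"), "missing_cov")
})

test_that("nested-model bookkeeping: delta AIC = 2 * dparams - LR", {
  d <- simulate_aft(400, intercept = 5, beta = c(v = -0.8), sigma = 0.4,
                    cap = 300, seed = 61)
  f <- fit_aft(d, "v")
  expect_equal(f$delta_aic, 2 * 1 - f$lr_stat, tolerance = 1e-9)
  expect_gte(f$lr_stat, 0)
})

test_that("predicted survival curves have the log-logistic properties", {
  d <- simulate_aft(500, intercept = 5, beta = c(dfa = -2), sigma = 0.3,
                    cap = 300, seed = 77)
  f <- fit_aft(d, "dfa")
  nd <- data.frame(dfa = c(-1, 0, 1))
  tmed <- exp(sum(unname(f$coefficients))) # median time at dfa = 1
  times <- sort(c(0, tmed, seq(10, 400, by = 10)))
  S <- predict_survival(f, nd, times)
  expect_true(all(S >= 0 & S <= 1))
  expect_equal(unname(S[1, ]), c(1, 1, 1))
  # at the covariate-specific median, survival is exactly 0.5
  expect_equal(S[which(times == tmed), 3], 0.5, tolerance = 1e-9)
  # monotone non-increasing in t
  expect_true(all(apply(S, 2, function(col) all(diff(col) <= 1e-12))))
  # negative coefficient: higher covariate -> uniformly lower curve
  mid <- times > 0
  expect_true(all(S[mid, 3] <= S[mid, 2]))
  expect_true(all(S[mid, 2] <= S[mid, 1]))
})

test_that("cluster-robust standard errors are produced by team", {
  d <- simulate_aft(300, intercept = 5, beta = c(v = -1), sigma = 0.35,
                    cap = 300, seed = 91)
  d$team <- rep(1:10, each = 30)
  f <- fit_aft(d, "v")
  expect_false(is.null(f$cluster_se))
  expect_length(f$cluster_se, 3)
  expect_true(all(f$cluster_se > 0))
})
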