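# Log-logistic accelerated failure time (AFT) model with right censoring.
# Trial durations enter as log t = X beta + sigma * eps with standard
# logistic errors; successful trials are events, trials that hit the cap
# are right-censored at it. The likelihood, gradient, and fitting are
# implemented here; survival::survreg serves as an independent cross-check
# in the test suite only.

#' Log-logistic AFT log-likelihood
#'
#' With `z = (log(t) - X beta) / sigma`, event records contribute the
#' logistic log-density of `log t` and censored records the log-survival
#' `-log(1 + e^z)`. `params` is `c(beta, log(sigma))`.
#'
#' @param params Numeric vector: regression coefficients on the log-time
#'   scale followed by the log of the scale parameter.
#' @param duration Positive durations (s).
#' @param event Logical; `TRUE` = observed completion, `FALSE` = censored.
#' @param X Design matrix (first column typically the intercept).
#' @return The log-likelihood (scalar).
#' @export
aft_loglik <- function(params, duration, event, X) {
  if (any(duration <= 0)) {
    stop("aft_loglik: durations must be positive", call. = FALSE)
  }
  p <- ncol(X)
  beta <- params[seq_len(p)]
  sigma <- exp(params[p + 1L])
  z <- (log(duration) - drop(X %*% beta)) / sigma
  ll_event <- dlogis(z, log = TRUE) - log(sigma)
  ll_cens <- plogis(z, lower.tail = FALSE, log.p = TRUE)
  sum(ifelse(event, ll_event, ll_cens))
}

# analytic gradient of aft_loglik in c(beta, log sigma)
aft_score <- function(params, duration, event, X) {
  p <- ncol(X)
  beta <- params[seq_len(p)]
  sigma <- exp(params[p + 1L])
  z <- (log(duration) - drop(X %*% beta)) / sigma
  pr <- plogis(z)
  # d loglik / dz, per record
  dz <- ifelse(event, 1 - 2 * pr, -pr)
  g_beta <- -X * (dz / sigma)
  g_logsigma <- ifelse(event, -dz * z - 1, -dz * z)
  cbind(g_beta, g_logsigma)
}

aft_gradient <- function(params, duration, event, X) {
  colSums(aft_score(params, duration, event, X))
}

#' Fit a log-logistic AFT model to censored trial durations
#'
#' Maximum likelihood via BFGS with the analytic gradient and several
#' dispersed starts (intercept from the log median duration, scale from an
#' IQR heuristic). Standard errors come from the inverse of the numerical
#' Hessian at the optimum; when `data` has a `team` column, cluster-robust
#' (sandwich) standard errors by team are also reported. A nested
#' intercept-only null fit supplies the likelihood-ratio statistic and the
#' AIC difference.
#'
#' @param data Data frame with columns `duration` (s), `event` (logical or
#'   0/1), the covariates named in `covariates`, and optionally `team`.
#' @param covariates Character vector of covariate column names (may be
#'   empty for the null model).
#' @param grad_tol Convergence criterion: maximum absolute gradient
#'   component at the optimum.
#' @return A `herd_aft` object: `coefficients`, `scale`, `se`,
#'   `cluster_se` (or `NULL`), `loglik`, `aic`, `n`, `n_events`,
#'   `lr_stat`/`lr_df`/`lr_p` and `delta_aic` versus the null fit (for
#'   models with covariates), `vcov`, `converged`.
#' @export
fit_aft <- function(data, covariates = character(), grad_tol = 1e-5) {
  stopifnot(is.data.frame(data), all(c("duration", "event") %in% names(data)))
  duration <- as.numeric(data$duration)
  event <- as.logical(data$event)
  if (any(duration <= 0)) stop("fit_aft: durations must be positive", call. = FALSE)
  if (anyNA(duration) || anyNA(event)) stop("fit_aft: missing values", call. = FALSE)
  if (!any(event)) {
    stop("fit_aft: no events; the model is not identifiable from censored ",
         "records alone (the likelihood increases without bound)",
         call. = FALSE)
  }
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov)) {
    stop("fit_aft: covariate(s) not in `data`: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, covariates, drop = FALSE]))
  if (qr(X)$rank < ncol(X)) {
    stop("fit_aft: design matrix is rank deficient", call. = FALSE)
  }

  y <- log(duration)
  s0 <- max(stats::IQR(y) / 2, 0.05)
  base_start <- c(stats::median(y), rep(0, length(covariates)), log(s0))
  starts <- list(
    base_start,
    base_start + c(0.5, rep(0, length(covariates)), log(2)),
    base_start + c(-0.5, rep(0, length(covariates)), log(0.5))
  )

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, fn = aft_loglik, gr = aft_gradient,
            duration = duration, event = event, X = X,
            method = "BFGS",
            control = list(fnscale = -1, maxit = 500, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value > best$value)) best <- fit
  }
  if (is.null(best)) {
    stop("fit_aft: optimization failed from all starts", call. = FALSE)
  }
  grad <- aft_gradient(best$par, duration, event, X)
  converged <- max(abs(grad)) < grad_tol

  H <- stats::optimHess(best$par, fn = aft_loglik, gr = aft_gradient,
                        duration = duration, event = event, X = X)
  vcov <- tryCatch(solve(-H), error = function(e) {
    matrix(NA_real_, length(best$par), length(best$par))
  })
  se <- sqrt(pmax(diag(vcov), 0))
  p <- ncol(X)
  k <- p + 1L # parameters including scale
  ll <- best$value
  aic <- -2 * ll + 2 * k

  coefs <- best$par[seq_len(p)]
  names(coefs) <- colnames(X)
  names(se) <- c(colnames(X), "log(scale)")

  cluster_se <- NULL
  if ("team" %in% names(data) && !anyNA(vcov)) {
    sc <- aft_score(best$par, duration, event, X)
    meat <- Reduce(`+`, lapply(split.data.frame(sc, data$team), function(m) {
      g <- colSums(m)
      tcrossprod(g)
    }))
    sand <- vcov %*% meat %*% vcov
    cluster_se <- sqrt(pmax(diag(sand), 0))
    names(cluster_se) <- names(se)
  }

  out <- structure(list(
    coefficients = coefs,
    scale = exp(best$par[p + 1L]),
    se = se,
    cluster_se = cluster_se,
    vcov = vcov,
    loglik = ll,
    aic = aic,
    n = length(duration),
    n_events = sum(event),
    covariates = covariates,
    converged = converged,
    par = best$par
  ), class = "herd_aft")

  if (length(covariates)) {
    null_fit <- fit_aft(data[c("duration", "event")], character(), grad_tol)
    out$null_loglik <- null_fit$loglik
    out$null_aic <- null_fit$aic
    out$lr_stat <- 2 * (ll - null_fit$loglik)
    out$lr_df <- length(covariates)
    out$lr_p <- stats::pchisq(out$lr_stat, out$lr_df, lower.tail = FALSE)
    out$delta_aic <- aic - null_fit$aic
  }
  out
}

#' @export
print.herd_aft <- function(x, ...) {
  cat("<herd_aft> log-logistic AFT |", x$n, "records,", x$n_events,
      "events\n")
  tab <- cbind(estimate = x$coefficients,
               se = x$se[seq_along(x$coefficients)])
  print(round(tab, 4))
  cat("scale:", format(x$scale, digits = 4),
      "| loglik:", format(x$loglik, digits = 6),
      "| AIC:", format(x$aic, digits = 6), "\n")
  if (!is.null(x$lr_stat)) {
    cat("LR chi-sq vs null:", format(x$lr_stat, digits = 4),
        "on", x$lr_df, "df, p =", format.pval(x$lr_p, digits = 3),
        "| delta AIC:", format(x$delta_aic, digits = 4), "\n")
  }
  if (!x$converged) cat("WARNING: gradient tolerance not met\n")
  invisible(x)
}

#' Predicted log-logistic survival curves
#'
#' `S(t | x) = 1 / (1 + (t / exp(x beta))^(1 / sigma))`: monotone
#' non-increasing in `t`, `S(0) = 1`, and `S` equals 0.5 exactly at the
#' median `exp(x beta)`.
#'
#' @param fit A `herd_aft` from [fit_aft()].
#' @param newdata Data frame of covariate values (one row per curve); may
#'   be omitted for the intercept-only curve.
#' @param times Non-negative evaluation times (s).
#' @return Matrix `length(times) x nrow(newdata)` of survival
#'   probabilities.
#' @export
predict_survival <- function(fit, newdata = NULL, times) {
  stopifnot(inherits(fit, "herd_aft"), all(times >= 0))
  if (is.null(newdata)) newdata <- as.data.frame(matrix(nrow = 1L, ncol = 0L))
  X <- cbind(1, as.matrix(newdata[, fit$covariates, drop = FALSE]))
  mu <- drop(X %*% fit$coefficients)
  out <- vapply(mu, function(m) {
    s <- ifelse(times == 0, 1,
                plogis((log(times) - m) / fit$scale, lower.tail = FALSE))
    as.numeric(s)
  }, numeric(length(times)))
  matrix(out, nrow = length(times))
}

#' Simulate records from a log-logistic AFT model
#'
#' Covariates are standard normal (or supplied), true completion times are
#' `exp(intercept + X beta + sigma * logistic)`, and times above `cap` are
#' right-censored at it — the same censoring treatment the trial pipeline
#' applies at the trial duration ceiling.
#'
#' @param n Number of records.
#' @param intercept,beta,sigma True parameters (`beta` named by covariate).
#' @param cap Censoring ceiling (s).
#' @param covariates Optional data frame of covariate values.
#' @param seed Optional seed (isolated from the caller's RNG state).
#' @return Data frame with `duration`, `event`, and covariate columns.
#' @export
simulate_aft <- function(n, intercept, beta = numeric(), sigma, cap = Inf,
                         covariates = NULL, seed = NULL) {
  draw <- function() {
    if (is.null(covariates) && length(beta)) {
      covariates <- as.data.frame(matrix(rnorm(n * length(beta)), n,
                                         dimnames = list(NULL, names(beta))))
    }
    lin <- intercept +
      if (length(beta)) drop(as.matrix(covariates) %*% beta) else 0
    t_true <- exp(lin + sigma * stats::rlogis(n))
    out <- data.frame(duration = pmin(t_true, cap), event = t_true <= cap)
    if (length(beta)) out <- cbind(out, covariates)
    out
  }
  if (is.null(seed)) draw() else stream_do(rng_stream(seed), draw)
}
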