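#' Flatten a trial log to a long-format table
#'
#' One row per logged sample: `time_s`, per-player `p<i>_x`, `p<i>_y`,
#' `p<i>_head` columns, and per-TA `ta<k>_x`, `ta<k>_y`, `ta<k>_status`
#' columns (status as label strings).
#'
#' @param x A `herd_trial_log`.
#' @param row.names,optional,... Ignored; present for the S3 generic.
#' @return A `data.frame`.
#' @export
as.data.frame.herd_trial_log <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  out <- list(time_s = x$time)
  for (i in 1:3) {
    out[[sprintf("p%d_x", i)]] <- x$player_x[, i]
    out[[sprintf("p%d_y", i)]] <- x$player_y[, i]
    out[[sprintf("p%d_head", i)]] <- x$player_head[, i]
  }
  k <- ncol(x$ta_x)
  for (j in seq_len(k)) {
    out[[sprintf("ta%02d_x", j)]] <- x$ta_x[, j]
    out[[sprintf("ta%02d_y", j)]] <- x$ta_y[, j]
    out[[sprintf("ta%02d_status", j)]] <- status_label(x$ta_status[, j])
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Write / read a trial log as CSV plus JSON manifest
#'
#' The CSV holds the long-format table of [as.data.frame.herd_trial_log()]
#' with all numeric fields formatted so that they round-trip exactly
#' (`%.17g`); the sidecar manifest (same path with extension `.json`) stores
#' the world configuration, policy configurations, seed, outcome, duration,
#' and condition labels. `read_trial_log(write_trial_log(log, path))`
#' reproduces `log` exactly.
#'
#' @param log A `herd_trial_log`.
#' @param path CSV file path (the manifest path is derived from it).
#' @return `write_trial_log` returns `path` invisibly; `read_trial_log`
#'   returns a `herd_trial_log`.
#' @export
write_trial_log <- function(log, path) {
  stopifnot(inherits(log, "herd_trial_log"))
  df <- as.data.frame(log)
  num <- vapply(df, is.numeric, logical(1L))
  for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
  data.table::fwrite(df, path, quote = FALSE)
  manifest <- list(
    sample_rate = log$sample_rate,
    outcome = log$outcome,
    duration = log$duration,
    seed = log$seed,
    condition = log$condition,
    config = unclass(log$config),
    policies = lapply(log$policies, unclass)
  )
  jsonlite::write_json(manifest, manifest_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

manifest_path <- function(path) sub("\\.[Cc][Ss][Vv]$", ".json", path)

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  mp <- manifest_path(path)
  if (!file.exists(path)) stop("trial log not found: ", path, call. = FALSE)
  if (!file.exists(mp)) stop("manifest not found: ", mp, call. = FALSE)
  man <- jsonlite::read_json(mp, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  df <- data.table::fread(path, data.table = FALSE)
  k <- as.integer(man$config$n_targets)

  need <- c("time_s",
            as.vector(t(outer(1:3, c("x", "y", "head"),
                              function(i, s) sprintf("p%d_%s", i, s)))),
            as.vector(t(outer(seq_len(k), c("x", "y", "status"),
                              function(j, s) sprintf("ta%02d_%s", j, s)))))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("trial log schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(need, grep("_status$", need, value = TRUE))
  for (cn in num_cols) {
    v <- df[[cn]]
    if (!is.numeric(v) || anyNA(v)) {
      stop("trial log schema error: column `", cn,
           "` is non-numeric or truncated (row ",
           if (is.numeric(v)) which(is.na(v))[1L] else 1L, ")", call. = FALSE)
    }
  }
  status_cols <- grep("_status$", need, value = TRUE)
  sm <- matrix(NA_integer_, nrow(df), k)
  for (j in seq_len(k)) {
    lab <- df[[status_cols[j]]]
    code <- TA_STATUS[lab]
    if (anyNA(code)) {
      stop("trial log schema error: unknown status label in `",
           status_cols[j], "` (row ", which(is.na(code))[1L], ")",
           call. = FALSE)
    }
    sm[, j] <- code
  }

  wcfg <- man$config
  wcfg$containment_center <- as.numeric(wcfg$containment_center)
  wcfg$n_targets <- as.integer(wcfg$n_targets)
  class(wcfg) <- "herd_world_config"
  pols <- lapply(man$policies, function(p) {
    p$global_info <- isTRUE(p$global_info)
    class(p) <- "herd_policy_config"
    p
  })

  mat <- function(cols) {
    m <- as.matrix(df[cols])
    dimnames(m) <- NULL
    m
  }
  structure(list(
    sample_rate = man$sample_rate,
    time = df$time_s,
    player_x = mat(sprintf("p%d_x", 1:3)),
    player_y = mat(sprintf("p%d_y", 1:3)),
    player_head = mat(sprintf("p%d_head", 1:3)),
    ta_x = mat(sprintf("ta%02d_x", seq_len(k))),
    ta_y = mat(sprintf("ta%02d_y", seq_len(k))),
    ta_status = sm,
    outcome = man$outcome,
    duration = man$duration,
    condition = man$condition,
    config = wcfg,
    policies = pols,
    seed = man$seed
  ), class = "herd_trial_log")
}

#' Write a fluctuation series as a two-column CSV
#'
#' Columns `time_s` (sample times at the series rate) and `value_rad`.
#'
#' @param series A `herd_angle_series` (see [displacement_angle_series()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_angle_series <- function(series, path) {
  stopifnot(inherits(series, "herd_angle_series"))
  df <- data.frame(
    time_s = sprintf("%.17g", seq_along(series$values) / series$sample_rate),
    value_rad = sprintf("%.17g", series$values)
  )
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}
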