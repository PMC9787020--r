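#' Plan a seeded batch over the emulated task manipulations
#'
#' Cells cross the emulated Visibility (`sense_radius` 10 m fog vs 150 m
#' clear), HUD (`global_info`), and Target Number (9 vs 18) manipulations;
#' the scripted search strategy is a separate factor so policy effects can
#' be studied orthogonally. The default cell set is the full 2 x 2 x 2
#' design under `partitioned_sweep`.
#'
#' @param cells Data frame with columns `sense_radius`, `global_info`,
#'   `n_targets`, `strategy`, and optionally `label`.
#' @param trials_per_cell Replicates per cell (>= 1).
#' @param root_seed Integer root seed; the seed of cell `i`, replicate `r`
#'   is `derive_seed(root_seed, i, r)`.
#' @param output_dir Optional directory; when given, every trial log and
#'   manifest is written there.
#' @return A `herd_experiment_plan`.
#' @export
experiment_plan <- function(cells = default_cells(),
                            trials_per_cell = 2,
                            root_seed = 1,
                            output_dir = NULL) {
  need <- c("sense_radius", "global_info", "n_targets", "strategy")
  if (!is.data.frame(cells) || !all(need %in% names(cells))) {
    stop("experiment_plan: `cells` must contain columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (trials_per_cell < 1) {
    stop("experiment_plan: `trials_per_cell` must be >= 1", call. = FALSE)
  }
  if (is.null(cells$label)) {
    cells$label <- sprintf("%s_%s_%02dTA_%s",
                           ifelse(cells$sense_radius >= 150, "clear", "fog"),
                           ifelse(cells$global_info, "hud", "compass"),
                           cells$n_targets, cells$strategy)
  }
  if (anyDuplicated(cells$label)) {
    stop("experiment_plan: cell labels must be unique", call. = FALSE)
  }
  structure(list(cells = cells,
                 trials_per_cell = as.integer(trials_per_cell),
                 root_seed = as.integer(root_seed),
                 output_dir = output_dir),
            class = "herd_experiment_plan")
}

#' @rdname experiment_plan
#' @export
default_cells <- function() {
  g <- expand.grid(sense_radius = c(10, 150),
                   global_info = c(FALSE, TRUE),
                   n_targets = c(9L, 18L),
                   KEEP.OUT.ATTRS = FALSE)
  g$strategy <- "partitioned_sweep"
  g
}

#' Run a planned batch and compute all per-trial measures
#'
#' For every cell x replicate: derive the trial seed, simulate the trial,
#' and compute the trial duration and outcome, the proportion of
#' overlapping search area, and each player's displacement-angle and
#' head-orientation-change DFA exponents. Measurement failures (e.g., a
#' fluctuation series too short for DFA after a very fast success) are
#' recorded per trial in `dfa_note` and do not stop the run. The result is
#' fully reproducible from the plan alone.
#'
#' @param plan A [experiment_plan()].
#' @param world_args Named list of extra [world_config()] arguments applied
#'   to every cell (e.g., a non-default `drag_coefficient`).
#' @param verbose Print one progress line per trial.
#' @return Data frame with one row per trial: condition labels, `seed`,
#'   `outcome`, `duration`, `overlap`, per-player `dfa_disp_1..3` and
#'   `dfa_head_1..3`, their team means, and `dfa_note`.
#' @export
run_experiment <- function(plan, world_args = list(), verbose = FALSE) {
  stopifnot(inherits(plan, "herd_experiment_plan"))
  cells <- plan$cells
  out_dir <- plan$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  rows <- vector("list", nrow(cells) * plan$trials_per_cell)
  ri <- 0L
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    wcfg <- do.call(world_config,
                    c(list(n_targets = cell$n_targets), world_args))
    pols <- replicate(3, policy_config(
      strategy = cell$strategy,
      sense_radius = cell$sense_radius,
      global_info = cell$global_info
    ), simplify = FALSE)
    for (r in seq_len(plan$trials_per_cell)) {
      ri <- ri + 1L
      seed <- derive_seed(plan$root_seed, ci, r)
      log <- run_trial(wcfg, pols, seed)
      if (!is.null(out_dir)) {
        write_trial_log(log, file.path(out_dir,
                                       sprintf("%s_r%02d.csv", cell$label, r)))
      }
      ov <- tryCatch(trial_overlap(log)$proportion, error = function(e) NA_real_)
      dfa_disp <- rep(NA_real_, 3L)
      dfa_head <- rep(NA_real_, 3L)
      note <- ""
      for (p in 1:3) {
        dfa_disp[p] <- tryCatch(
          dfa_alpha(prepare_angle_series(log, p, "displacement_angle"))$alpha,
          error = function(e) {
            note <<- conditionMessage(e)
            NA_real_
          })
        dfa_head[p] <- tryCatch(
          dfa_alpha(prepare_angle_series(log, p, "head_orientation_change"))$alpha,
          error = function(e) {
            note <<- conditionMessage(e)
            NA_real_
          })
      }
      rows[[ri]] <- data.frame(
        cell = cell$label,
        sense_radius = cell$sense_radius,
        global_info = cell$global_info,
        n_targets = cell$n_targets,
        strategy = cell$strategy,
        replicate = r,
        seed = seed,
        outcome = log$outcome,
        duration = log$duration,
        overlap = ov,
        dfa_disp_1 = dfa_disp[1L], dfa_disp_2 = dfa_disp[2L],
        dfa_disp_3 = dfa_disp[3L],
        dfa_head_1 = dfa_head[1L], dfa_head_2 = dfa_head[2L],
        dfa_head_3 = dfa_head[3L],
        dfa_disp_mean = mean(dfa_disp, na.rm = TRUE),
        dfa_head_mean = mean(dfa_head, na.rm = TRUE),
        dfa_note = note,
        stringsAsFactors = FALSE
      )
      if (verbose) {
        message(sprintf("[%s r%02d seed %d] %s %.1f s, overlap %.3f",
                        cell$label, r, seed, log$outcome, log$duration,
                        ov))
      }
    }
  }
  do.call(rbind, rows)
}

#' Per-cell summaries with bootstrap intervals
#'
#' Means and percentile bootstrap confidence intervals per cell for trial
#' duration, overlap proportion, and the two team-mean DFA exponents.
#'
#' @param metrics Output of [run_experiment()].
#' @param boot Number of bootstrap resamples.
#' @param level Interval level.
#' @param seed Seed for the bootstrap resampling.
#' @return Data frame, one row per cell and measure.
#' @export
summarize_experiment <- function(metrics, boot = 2000, level = 0.95,
                                 seed = 1) {
  measures <- c("duration", "overlap", "dfa_disp_mean", "dfa_head_mean")
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  stream <- rng_stream(seed)
  out <- list()
  for (cl in unique(metrics$cell)) {
    sub <- metrics[metrics$cell == cl, ]
    for (m in measures) {
      v <- sub[[m]]
      v <- v[!is.na(v)]
      if (!length(v)) {
        out[[length(out) + 1L]] <- data.frame(
          cell = cl, measure = m, n = 0L, mean = NA_real_,
          lo = NA_real_, hi = NA_real_)
        next
      }
      bm <- stream_do(stream, function() {
        vapply(seq_len(boot), function(i) {
          mean(v[sample.int(length(v), replace = TRUE)])
        }, numeric(1L))
      })
      ci <- unname(quantile(bm, qs, type = 7))
      out[[length(out) + 1L]] <- data.frame(
        cell = cl, measure = m, n = length(v), mean = mean(v),
        lo = ci[1L], hi = ci[2L])
    }
  }
  do.call(rbind, out)
}

#' Qualitative direction checks across conditions
#'
#' Compares cell groups on the orderings the human study reported:
#' global-information (HUD) trials complete faster than compass trials,
#' clear-visibility faster than fog, 9 targets faster than 18, partitioned
#' search overlaps less than shared search, and trials with higher
#' team-mean displacement-angle DFA exponents complete faster (negative
#' Spearman association).
#'
#' @param metrics Output of [run_experiment()].
#' @return Data frame of comparisons with group means (or the correlation)
#'   and a logical `holds`.
#' @export
direction_checks <- function(metrics) {
  cmp <- function(name, a, b) {
    data.frame(check = name, value_a = mean(a, na.rm = TRUE),
               value_b = mean(b, na.rm = TRUE),
               holds = mean(a, na.rm = TRUE) < mean(b, na.rm = TRUE))
  }
  out <- list()
  if (length(unique(metrics$global_info)) > 1L) {
    out[[length(out) + 1L]] <- cmp(
      "duration: hud < compass",
      metrics$duration[metrics$global_info],
      metrics$duration[!metrics$global_info])
  }
  if (length(unique(metrics$sense_radius)) > 1L) {
    clear <- metrics$sense_radius >= 150
    out[[length(out) + 1L]] <- cmp(
      "duration: clear < fog",
      metrics$duration[clear], metrics$duration[!clear])
  }
  if (length(unique(metrics$n_targets)) > 1L) {
    out[[length(out) + 1L]] <- cmp(
      "duration: 9 < 18 targets",
      metrics$duration[metrics$n_targets == 9],
      metrics$duration[metrics$n_targets == 18])
  }
  if (all(c("partitioned_sweep", "shared_sweep") %in% metrics$strategy)) {
    out[[length(out) + 1L]] <- cmp(
      "overlap: partitioned < shared",
      metrics$overlap[metrics$strategy == "partitioned_sweep"],
      metrics$overlap[metrics$strategy == "shared_sweep"])
  }
  ok <- !is.na(metrics$dfa_disp_mean) & !is.na(metrics$duration)
  if (sum(ok) >= 3L && stats::sd(metrics$duration[ok]) > 0) {
    rho <- cor(metrics$dfa_disp_mean[ok], metrics$duration[ok],
               method = "spearman")
    out[[length(out) + 1L]] <- data.frame(
      check = "association: higher displacement DFA, shorter duration",
      value_a = rho, value_b = 0, holds = rho < 0)
  }
  do.call(rbind, out)
}
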