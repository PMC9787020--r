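# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# A full-length failed trial at study defaults (18 TAs, fog + compass,
# shared sweep): 300 s at 90 Hz -> 27,000 logged samples. Reused by the
# I/O, preparation, overlap, and simulator-contract tests.
full_fail_trial <- function() {
  if (is.null(.fixtures$full_fail)) {
    cfg <- world_config(n_targets = 18)
    pol <- replicate(3, policy_config(strategy = "shared_sweep",
                                      global_info = FALSE,
                                      sense_radius = 10),
                     simplify = FALSE)
    .fixtures$full_fail <- run_trial(cfg, pol, seed = 2024)
  }
  .fixtures$full_fail
}

# A quick small-world trial for schema/metadata tests.
small_trial <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- world_config(n_targets = 3, trial_max = 30)
    pol <- replicate(3, policy_config(strategy = "partitioned_sweep"),
                     simplify = FALSE)
    .fixtures$small <- run_trial(cfg, pol, seed = 11)
  }
  .fixtures$small
}

# Handmade ring-list polygons for overlap fixtures.
square_region <- function(x0, y0, side) {
  list(list(x = c(x0, x0 + side, x0 + side, x0),
            y = c(y0, y0, y0 + side, y0 + side)))
}
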